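# The 3x5 demonstration system: l1 solution spreads over coordinates 2, 3, 5
# while the sparsest solution lives on coordinates 4, 5. Values printed to a
# few decimals carry ~1e-3 input precision; exact re-solves of the stored
# system (frozen below from an independent linear-algebra route) are asserted
# tightly, printed reference values loosely.
example_l1 <- c(0.0, -0.034, 0.047, 0.0, 0.870)
example_sparsest <- c(0, 0, 0, -1.2372, 1.04858)
# numpy.linalg.solve on columns {3,4,5} of the stored system:
example_resolve <- c(0, 0, 5.53967256e-04, -1.22530756, 1.04719444)

test_that("system constructor enforces shape, rank and finiteness", {
  expect_s3_class(example_system(), "akron_system")
  expect_equal(example_system()$s, 2L)
  expect_error(underdetermined_system(diag(3), 1:3), "p > n")
  expect_error(underdetermined_system(matrix(c(1, 2, 2, 4, 3, 6), 2, 3), 1:2),
               "full row rank")
  expect_error(underdetermined_system(matrix(1:6, 2, 3), 1:3), "length")
  expect_error(underdetermined_system(matrix(rnorm(6), 2, 3), 1:2,
                                      noise_eps = -1), "nonnegative")
})

test_that("sparse solutions recompute their residual and keep hard zeros", {
  sys <- example_system()
  x <- c(0, 1, 0, 2, -1)
  sol <- sparse_solution(x, sys, zero_set = c(1, 3))
  expect_equal(sol$residual, sqrt(sum((sys$phi %*% x - sys$y)^2)),
               tolerance = 1e-12)
  expect_identical(sol$zero_set, c(1L, 3L))
  expect_gte(sol$num_zeros, length(sol$zero_set))
  expect_error(sparse_solution(c(1, 1, 0, 0, 0), sys, zero_set = 1),
               "exactly zero")
  expect_error(sparse_solution(x, sys, zero_set = 9), "1..p")
})

test_that("basis pursuit finds the minimum-l1 solution", {
  sol <- basis_pursuit(example_system())
  expect_lt(max(abs(sol$x - example_l1)), 1e-3)
  expect_lte(sol$residual, 1e-8)

  # a padded identity: the third column can never help the l1 objective
  sys <- underdetermined_system(cbind(diag(2), c(0, 0)), c(1, 2))
  expect_equal(basis_pursuit(sys)$x, c(1, 2, 0), tolerance = 1e-9)

  # 1-sparse recovery, checked against exhaustive single-support fits
  for (seed in 1:5) {
    ps <- planted_system(p = 8, n = 4, k_nz = 1, seed = seed,
                         wmin = 2, wmax = 3)
    single_fit <- sapply(1:8, function(j) {
      phi_j <- ps$system$phi[, j]
      a <- sum(phi_j * ps$system$y) / sum(phi_j^2)
      sqrt(sum((phi_j * a - ps$system$y)^2))
    })
    expect_equal(which.min(single_fit), ps$support)
    sol <- basis_pursuit(ps$system)
    expect_lt(max(abs(sol$x - ps$x0)), 1e-7)
  }
})

test_that("basis pursuit is l1-optimal against kernel perturbations", {
  set.seed(11)
  ps <- planted_system(p = 10, n = 5, k_nz = 2, seed = 3)
  sol <- basis_pursuit(ps$system)
  K <- kernel_basis(ps$system$phi)
  W <- matrix(rnorm(1000 * ncol(K)), 1000, ncol(K))
  for (i in 1:1000) {
    z <- sol$x + as.numeric(K %*% W[i, ])
    expect_gte(sum(abs(z)) + 1e-6, sol$l1)
  }
})

test_that("zero-set solves reduce, solve and re-embed correctly", {
  sys <- example_system()
  sol <- solve_with_zero_set(sys, c(1, 2))
  expect_lt(max(abs(sol$x - example_resolve)), 1e-6)
  expect_lte(sol$residual, 1e-8)

  # single-equation case
  s2 <- underdetermined_system(matrix(c(1, 2), 1, 2), 4)
  expect_equal(solve_with_zero_set(s2, 1)$x, c(0, 2))
  expect_equal(solve_with_zero_set(s2, 1)$residual, 0)

  # residual always matches an independent recomputation
  sol2 <- solve_with_zero_set(sys, c(1, 4))
  expect_equal(sol2$residual,
               sqrt(sum((sys$phi %*% sol2$x - sys$y)^2)), tolerance = 1e-10)

  expect_error(solve_with_zero_set(sys, 1), "exactly s = 2")
  expect_error(solve_with_zero_set(sys, c(1, 2, 3)), "exactly s = 2")
})

test_that("exact kernel reconstruction matches a support-enumeration oracle", {
  # demonstration system: zeros restored at coordinates 1..3
  sol <- kron_exact(example_system())
  expect_lt(max(abs(sol$x - example_resolve)), 1e-6)
  expect_identical(sol$num_zeros, 3L)

  # zero right-hand side: nothing is sparser than the zero vector
  set.seed(5)
  sys0 <- underdetermined_system(matrix(rnorm(12), 3, 4), rep(0, 3))
  expect_equal(kron_exact(sys0)$x, rep(0, 4))
  expect_identical(kron_exact(sys0)$num_zeros, 4L)

  # planted 2-sparse rows in 3x6 systems, against the independent oracle
  for (seed in 1:10) {
    ps <- planted_system(p = 6, n = 3, k_nz = 2, seed = seed)
    got <- kron_exact(ps$system)
    want <- oracle_sparsest(ps$system)
    expect_equal(sum(got$x != 0), want$nnz)
    expect_lt(max(abs(got$x - want$x)), 1e-8)
  }

  big <- planted_system(p = 25, n = 9, k_nz = 2, seed = 1)
  expect_error(kron_exact(big$system), "enumeration cap")
})

test_that("the delta-neighborhood search interpolates l1 and exact KRON", {
  sys <- example_system()
  seed_sol <- basis_pursuit(sys)
  sol <- akron(sys, seed_sol, delta = 1)
  expect_identical(attr(sol, "n_combinations"), 3L)
  expect_lt(max(abs(sol$x - example_resolve)), 1e-6)

  # delta = 0 is the single zero set of the s smallest seed magnitudes
  for (seed in 1:5) {
    ps <- planted_system(p = 8, n = 5, k_nz = 3, seed = seed)
    l1 <- basis_pursuit(ps$system)
    d0 <- akron(ps$system, l1, delta = 0)
    zs <- sort(order(abs(l1$x), seq_along(l1$x))[1:ps$system$s])
    expect_equal(d0$x, solve_with_zero_set(ps$system, zs)$x)
  }

  # delta = n recovers full-enumeration behavior
  for (seed in 1:8) {
    ps <- planted_system(p = 7, n = 4, k_nz = 2, seed = seed + 100)
    full <- akron(ps$system, basis_pursuit(ps$system), delta = ps$system$n)
    exact <- kron_exact(ps$system)
    expect_identical(full$num_zeros, exact$num_zeros)
    expect_lte(full$residual, 1e-8)
  }

  expect_error(akron(sys, seed_sol, delta = 4), "must not exceed n")
  expect_error(akron(sys, seed_sol, delta = 2, max_comb = 2), "max_comb")
})

test_that("akron residual is non-increasing in the neighborhood size", {
  for (seed in 1:25) {
    ps <- planted_system(p = 9, n = 5, k_nz = 3, seed = seed,
                         obs_sigma = 0.05)
    l1seed <- basis_pursuit(ps$system, tol = 1)  # noisy: LP stays feasible-ish
    res <- sapply(0:3, function(d)
      akron(ps$system, l1seed, delta = d)$residual)
    expect_true(all(diff(res) <= 1e-12))
  }
})

test_that("the adaptive noisy search stops at the noise threshold", {
  phi <- example_system()$phi
  y <- example_system()$y

  # an infinite threshold accepts the first (delta = 0) candidate
  sys_inf <- underdetermined_system(phi, y, noise_eps = Inf)
  l1 <- basis_pursuit(sys_inf)
  s_inf <- akron_noisy(sys_inf, l1)
  expect_identical(attr(s_inf, "delta"), 0L)
  expect_equal(s_inf$x, akron(sys_inf, l1, delta = 0)$x)

  # the demonstration system is noiseless-consistent, so the delta = 0
  # candidate already beats any positive threshold and is adopted at once
  sys_eps <- underdetermined_system(phi, y, noise_eps = 1e-6)
  s_eps <- akron_noisy(sys_eps, basis_pursuit(sys_eps))
  expect_true(attr(s_eps, "converged"))
  expect_identical(attr(s_eps, "delta"), 0L)
  expect_lte(s_eps$residual, 1e-6)

  # genuinely noisy planted systems: whenever the l1 seed sees the planted
  # support (the informative-seed regime the optimality bounds assume), the
  # accepted zero set avoids that support
  checked <- 0L; seed <- 0L
  while (checked < 5L) {
    seed <- seed + 1L
    set.seed(seed)
    p <- 8; n <- 5; k_nz <- 2
    phi_r <- matrix(rnorm(n * p), n, p)
    x0 <- numeric(p); supp <- sample.int(p, k_nz)
    x0[supp] <- runif(k_nz, 1, 2) * sample(c(-1, 1), k_nz, TRUE)
    v <- rnorm(n, 0, 1e-3)
    sys_n <- underdetermined_system(phi_r, as.vector(phi_r %*% x0) + v,
                                    noise_eps = sqrt(sum(v^2)))
    l1_n <- basis_pursuit(sys_n)
    if (any(abs(l1_n$x[supp]) < 0.5)) next  # seed missed the support
    checked <- checked + 1L
    out <- akron_noisy(sys_n, l1_n)
    expect_true(attr(out, "converged"))
    expect_length(intersect(out$zero_set, supp), 0)
  }

  expect_error(akron_noisy(example_system(), l1), "noise_eps")

  # nested mode pins the whole escalating pool to zero
  s_nested <- akron_noisy(sys_eps, basis_pursuit(sys_eps), mode = "nested")
  expect_gte(length(s_nested$zero_set), sys_eps$s)
})

test_that("optimality-bound calculators follow their closed forms", {
  # threshold eps/sqrt(k-s+1) = 0.0707 catches the three small entries
  expect_identical(delta_bound_closeness(c(0, 0, 0, 5, 5), eps = 0.1,
                                         k = 3, s = 2), 1L)
  # eps = 0 counts only exact zeros
  expect_identical(delta_bound_closeness(c(0, 1e-9, 1, 2, 2), eps = 0,
                                         k = 3, s = 2), 0L)
  # nothing under the threshold: clamped at zero
  expect_identical(delta_bound_closeness(c(1, 1, 1, 1, 1), eps = 0.1,
                                         k = 3, s = 2), 0L)
  expect_error(delta_bound_closeness(1:5, eps = 0.1, k = 2, s = 2), "k > s")

  expect_identical(delta_bound_magnitude(0.4, 1), 0L)    # eps < eta/2
  expect_identical(delta_bound_magnitude(0, 1), 0L)
  expect_identical(delta_bound_magnitude(0.75, 1), 9L)   # (0.75/0.25)^2
  expect_error(delta_bound_magnitude(1, 1), "inapplicable")
})

test_that("the closeness bound's neighborhood suffices for optimality", {
  hits <- 0L
  for (seed in 1:50) {
    ps <- planted_system(p = 8, n = 5, k_nz = 2, seed = seed + 400,
                         wmin = 1, wmax = 2)
    k <- sum(ps$x0 == 0)              # zeros of the planted solution
    l1 <- basis_pursuit(ps$system)
    eps <- sqrt(sum((l1$x - ps$x0)^2)) + 1e-12
    d <- min(delta_bound_closeness(l1$x, eps, k = k, s = ps$system$s),
             ps$system$n)
    out <- akron(ps$system, l1, delta = d)
    if (out$num_zeros >= k) hits <- hits + 1L
  }
  expect_identical(hits, 50L)
})
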