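# Shared fixtures: planted sparse systems and an independent brute-force
# sparsest-solution oracle (enumerates supports and least-squares fits them,
# a different route than the package's zero-set solves).

planted_system <- function(p, n, k_nz, seed, wmin = 0.5, wmax = 1.5,
                           obs_sigma = 0, noise_eps = 0) {
  set.seed(seed)
  phi <- matrix(rnorm(n * p), n, p)
  x0 <- numeric(p)
  supp <- sort(sample.int(p, k_nz))
  x0[supp] <- runif(k_nz, wmin, wmax) * sample(c(-1, 1), k_nz, replace = TRUE)
  y <- as.vector(phi %*% x0)
  if (obs_sigma > 0) y <- y + rnorm(n, 0, obs_sigma)
  list(system = underdetermined_system(phi, y, noise_eps = noise_eps),
       x0 = x0, support = supp)
}

# smallest-support exact solution by support enumeration + least squares
oracle_sparsest <- function(system, tol = 1e-8) {
  p <- system$p
  for (k in 0:system$n) {
    supports <- if (k == 0) list(integer(0)) else {
      cmb <- utils::combn(p, k)
      lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
    }
    for (supp in supports) {
      x <- numeric(p)
      if (k > 0) {
        co <- qr.coef(qr(system$phi[, supp, drop = FALSE]), system$y)
        co[is.na(co)] <- 0
        x[supp] <- co
      }
      if (sqrt(sum((system$phi %*% x - system$y)^2)) <= tol)
        return(list(x = x, nnz = sum(x != 0)))
    }
  }
  NULL
}

# orthonormal kernel basis of phi (for feasible perturbations)
kernel_basis <- function(phi) {
  sv <- svd(phi, nu = 0, nv = ncol(phi))
  sv$v[, (nrow(phi) + 1):ncol(phi), drop = FALSE]
}

# generic numerical minimizer of the sparsifying-projection objective,
# coordinate-wise (the objective is separable)
oracle_lasso_project <- function(a, alpha) {
  vapply(a, function(ai) {
    f <- function(z) (1 - alpha) * (ai - z)^2 + alpha * abs(z)
    stats::optimize(f, c(-abs(ai) - 1, abs(ai) + 1), tol = 1e-10)$minimum
  }, numeric(1))
}
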