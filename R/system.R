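#' Under-determined linear system
#'
#' Bundles a full-rank sensing matrix \eqn{\Phi} (\eqn{n \times p}, \eqn{p > n})
#' with an observation vector \eqn{y}, the kernel dimension \eqn{s = p - n},
#' and an optional noise threshold. This is the container all sparse solvers
#' ([basis_pursuit()], [kron_exact()], [akron()], [akron_noisy()]) operate on:
#' the solution set of \eqn{\Phi x = y} is an affine subspace of dimension
#' \eqn{s}, so fixing \eqn{s} correct zero positions makes the reduced system
#' square and uniquely solvable.
#'
#' @param phi numeric matrix with more columns than rows; must have full row
#'   rank (checked by QR decomposition).
#' @param y numeric vector of length `nrow(phi)`.
#' @param noise_eps nonnegative noise threshold \eqn{\epsilon}; `0` declares
#'   the system noiseless. Used by [akron_noisy()].
#' @param rank_tol tolerance passed to [qr()] for the rank check; default
#'   lets LAPACK choose.
#'
#' @return An object of class `"akron_system"`: a list with elements `phi`,
#'   `y`, `n`, `p`, `s` and `noise_eps`.
#' @examples
#' sys <- underdetermined_system(matrix(rnorm(15), 3, 5), rnorm(3))
#' sys$s  # kernel dimension 2
#' @export
underdetermined_system <- function(phi, y, noise_eps = 0, rank_tol = 1e-10) {
  phi <- as.matrix(phi)
  storage.mode(phi) <- "double"
  y <- as.numeric(y)
  n <- nrow(phi)
  p <- ncol(phi)
  if (!(p > n && n >= 1L))
    stop("need an under-determined system: p > n >= 1 (got n = ", n,
         ", p = ", p, ")")
  if (length(y) != n)
    stop("length(y) must equal nrow(phi)")
  if (anyNA(phi) || anyNA(y))
    stop("phi and y must be finite")
  rk <- qr(phi, tol = rank_tol)$rank
  if (rk < n)
    stop("phi must have full row rank ", n, " but has numerical rank ", rk)
  if (!is.numeric(noise_eps) || length(noise_eps) != 1L || noise_eps < 0)
    stop("noise_eps must be a single nonnegative number")
  structure(
    list(phi = phi, y = y, n = n, p = p, s = p - n, noise_eps = noise_eps),
    class = "akron_system"
  )
}

#' @export
print.akron_system <- function(x, ...) {
  cat(sprintf("Under-determined system: n = %d equations, p = %d unknowns, kernel dim s = %d\n",
              x$n, x$p, x$s))
  if (x$noise_eps > 0)
    cat(sprintf("  noisy mode, noise threshold eps = %g\n", x$noise_eps))
  invisible(x)
}

#' Candidate sparse solution of an under-determined system
#'
#' Wraps a solution vector together with the index set of entries that were
#' fixed to exactly zero by the solver, the recomputed residual
#' \eqn{\|\Phi x - y\|_2}, and the number of entries counted as zero.
#'
#' An entry is *counted* as zero when \eqn{|x_j| \le} `zero_tol` \eqn{\cdot
#' \max_j |x_j|}. The relative threshold deliberately absorbs limited input
#' precision: coefficients printed to a few decimals perturb a square solve
#' enough that an exactly-zero coordinate of the underlying solution
#' resurfaces as a small nonzero, and edge detection should not report it as
#' an interaction.
#'
#' @param x numeric solution vector of length `system$p`.
#' @param system the [underdetermined_system()] the solution refers to.
#' @param zero_set integer indices (1-based) of entries fixed to exactly
#'   zero; `x[zero_set]` must all be `0`.
#' @param zero_tol relative zero-counting tolerance (default `1e-3`).
#'
#' @return Object of class `"akron_solution"`: list with `x`, `zero_set`
#'   (sorted), `residual`, `num_zeros`, `l1`, `zero_tol`.
#' @seealso [solve_with_zero_set()], [akron()]
#' @export
sparse_solution <- function(x, system, zero_set = integer(0), zero_tol = 1e-3) {
  stopifnot(inherits(system, "akron_system"))
  x <- as.numeric(x)
  if (length(x) != system$p)
    stop("x must have length p = ", system$p)
  zero_set <- sort(unique(as.integer(zero_set)))
  if (length(zero_set) && (min(zero_set) < 1L || max(zero_set) > system$p))
    stop("zero_set indices must lie in 1..p")
  if (length(zero_set) && any(x[zero_set] != 0))
    stop("entries listed in zero_set must be exactly zero")
  structure(
    list(x = x,
         zero_set = zero_set,
         residual = sqrt(sum((system$phi %*% x - system$y)^2)),
         num_zeros = count_zeros(x, zero_tol),
         l1 = sum(abs(x)),
         zero_tol = zero_tol),
    class = "akron_solution"
  )
}

# number of entries at or below the relative zero threshold
count_zeros <- function(x, zero_tol) {
  m <- max(abs(x))
  sum(abs(x) <= zero_tol * m)
}

#' @export
print.akron_solution <- function(x, digits = 5, ...) {
  cat("Sparse solution (", length(x$x), " entries, ", x$num_zeros,
      " counted zero)\n", sep = "")
  cat("  x        =", paste(signif(x$x, digits), collapse = " "), "\n")
  cat("  zero_set = {", paste(x$zero_set, collapse = ", "), "}\n", sep = "")
  cat(sprintf("  residual = %.3e   l1 = %.5g\n", x$residual, x$l1))
  invisible(x)
}
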