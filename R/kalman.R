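#' State of one gene's incoming-edge vector
#'
#' The tracked state for gene \eqn{i} is its length-\eqn{p} incoming-edge
#' vector \eqn{a_i(k)} (positive entries activating, negative repressing)
#' with a \eqn{p \times p} error covariance. The dynamics are a Gaussian
#' random walk -- the agnostic model for slow topology rewiring -- and the
#' observations are expression rates of change seen through the transposed
#' expression matrix.
#'
#' @param a numeric state mean of length p.
#' @param P p x p covariance; symmetrized on input, must be positive
#'   semidefinite (smallest eigenvalue above `-1e-10 * trace`).
#' @param epoch integer epoch index the state refers to.
#' @return Object of class `"gene_state"`.
#' @export
gene_state <- function(a, P, epoch = 0L) {
  a <- as.numeric(a)
  P <- as.matrix(P)
  p <- length(a)
  if (!all(dim(P) == c(p, p))) stop("P must be ", p, " x ", p)
  if (max(abs(P - t(P))) > 1e-8 * (1 + max(abs(P))))
    stop("P must be symmetric")
  P <- (P + t(P)) / 2
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(sum(diag(P)), 1))
    stop("P must be positive semidefinite (min eigenvalue ", signif(min(ev), 3), ")")
  structure(list(a = a, P = P, epoch = as.integer(epoch)),
            class = "gene_state")
}

#' Kalman prediction step for the random-walk edge model
#'
#' The state transition is the identity plus process noise, so prediction
#' leaves the mean untouched and inflates the covariance by
#' `q_scale` \eqn{\cdot I}. Symmetry is re-enforced after the addition.
#'
#' @param state a [gene_state()].
#' @param q_scale nonnegative isotropic process-noise variance.
#' @return The predicted `"gene_state"` at `epoch + 1`.
#' @export
kf_predict <- function(state, q_scale) {
  stopifnot(inherits(state, "gene_state"), q_scale >= 0)
  P <- state$P + diag(q_scale, length(state$a))
  state$P <- (P + t(P)) / 2
  state$epoch <- state$epoch + 1L
  state
}

#' Kalman measurement update from one epoch of expression data
#'
#' Observations follow \eqn{y = X^\top a + v} with isotropic measurement
#' noise of variance `r_scale`: the observation matrix is the transposed
#' expression matrix \eqn{H = X^\top} (one row per time sample in the
#' epoch). The gain is obtained through a Cholesky solve of the innovation
#' covariance -- never an explicit inverse -- and the covariance is updated
#' in Joseph form, which preserves symmetry and positive semidefiniteness
#' under roundoff.
#'
#' @param state a [gene_state()] prior.
#' @param X p x n_k expression matrix for the epoch.
#' @param y length-n_k vector of observed expression rates of change.
#' @param r_scale positive isotropic observation-noise variance.
#' @return The posterior `"gene_state"`.
#' @export
kf_update <- function(state, X, y, r_scale) {
  stopifnot(inherits(state, "gene_state"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  p <- length(state$a)
  if (nrow(X) != p) stop("X must have p = ", p, " rows")
  nk <- ncol(X)
  if (length(y) != nk) stop("length(y) must equal ncol(X)")
  if (r_scale < 0) stop("r_scale must be nonnegative")
  H <- t(X)                               # n_k x p
  PHt <- state$P %*% t(H)                 # p x n_k
  S <- H %*% PHt + diag(r_scale, nk)
  S <- (S + t(S)) / 2
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("innovation covariance is numerically singular; ",
         "increase r_scale or reduce p0_scale")
  # K = P H' S^{-1} via two triangular solves
  K <- t(backsolve(ch, forwardsolve(t(ch), t(PHt))))
  innov <- y - as.numeric(H %*% state$a)
  a <- state$a + as.numeric(K %*% innov)
  IKH <- diag(p) - K %*% H
  P <- IKH %*% state$P %*% t(IKH) + K %*% (r_scale * diag(nk)) %*% t(K)
  gene_state(a, (P + t(P)) / 2, epoch = state$epoch)
}

#' Sparsifying projection of a Kalman estimate (soft thresholding)
#'
#' Projects an estimate onto the set of approximately sparse vectors by
#' minimizing \deqn{(1-\alpha)\,\|a_{k|k} - a\|_2^2 + \alpha\,\|a\|_1,}
#' whose exact minimizer is elementwise soft thresholding with threshold
#' \eqn{\lambda = \alpha / (2(1-\alpha))}. Small `alpha` stays close to the
#' Kalman estimate; `alpha` near 1 forces sparsity at the price of fidelity.
#'
#' @param a numeric vector (the filtered estimate).
#' @param alpha tradeoff in `[0, 1]`; at exactly 1 the quadratic term
#'   vanishes and the zero vector is returned with a warning.
#' @return Numeric vector of the same length.
#' @examples
#' lasso_project(c(1, -0.2, 0.05), alpha = 0.2)  # threshold 0.125
#' @export
lasso_project <- function(a, alpha) {
  stopifnot(is.numeric(a), is.numeric(alpha), length(alpha) == 1L)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (alpha == 1) {
    warning("alpha = 1 makes the objective ignore the estimate; ",
            "returning the zero vector")
    return(numeric(length(a)))
  }
  lambda <- alpha / (2 * (1 - alpha))
  sign(a) * pmax(abs(a) - lambda, 0)
}

#' Fixed-interval Rauch-Tung-Striebel smoother
#'
#' Backward pass refining the filtered states with information from later
#' epochs, for the identity-transition (random walk) model. With filtered
#' states \eqn{(a_{k|k}, P_{k|k})} and one-step predictions
#' \eqn{(a_{k+1|k}, P_{k+1|k})}, the smoother gain is
#' \eqn{G_k = P_{k|k} P_{k+1|k}^{-1}} and
#' \deqn{a_{k|T} = a_{k|k} + G_k (a_{k+1|T} - a_{k+1|k}),}
#' \deqn{P_{k|T} = P_{k|k} + G_k (P_{k+1|T} - P_{k+1|k}) G_k^\top.}
#' The last smoothed state equals the last filtered state.
#'
#' @param filtered list of [gene_state()]s, the forward-filtered sequence.
#' @param predicted list of the same length: `predicted[[k]]` is the prior
#'   (one-step prediction) that produced `filtered[[k]]`.
#' @return List of smoothed `"gene_state"`s.
#' @export
rts_smooth <- function(filtered, predicted) {
  T_ <- length(filtered)
  if (length(predicted) != T_)
    stop("filtered and predicted sequences must have equal length")
  if (T_ == 0L) stop("need at least one state")
  sm <- vector("list", T_)
  sm[[T_]] <- filtered[[T_]]
  if (T_ == 1L) return(sm)
  for (k in (T_ - 1L):1L) {
    Pf <- filtered[[k]]$P
    Ppred <- predicted[[k + 1L]]$P
    G <- t(solve(Ppred, Pf))             # Pf %*% Ppred^{-1}, Ppred symmetric
    a <- filtered[[k]]$a + as.numeric(G %*% (sm[[k + 1L]]$a - predicted[[k + 1L]]$a))
    P <- Pf + G %*% (sm[[k + 1L]]$P - Ppred) %*% t(G)
    P <- (P + t(P)) / 2
    # clip tiny negative eigenvalues from roundoff before validating
    sm[[k]] <- gene_state(a, psd_clip(P), epoch = filtered[[k]]$epoch)
  }
  sm
}

# project a symmetric matrix onto the PSD cone by eigenvalue clipping
psd_clip <- function(P) {
  e <- eigen(P, symmetric = TRUE)
  if (min(e$values) >= 0) return(P)
  e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
}

#' Finite-difference expression rates of change
#'
#' Estimates the time derivative of each gene's expression by central
#' differences at interior samples and one-sided differences at the ends.
#' When an epoch partition is supplied the differences never cross an epoch
#' boundary, so each developmental stage keeps its own boundary stencils --
#' expression need not be continuous across stages.
#'
#' @param expression p x m numeric matrix (genes in rows, time samples in
#'   columns).
#' @param sample_times strictly increasing vector of length m; defaults to
#'   unit spacing.
#' @param epochs optional partition: a list of integer column-index vectors
#'   covering `1..m` disjointly (see [as_epoch_partition()]).
#' @return p x m matrix of derivative estimates.
#' @export
compute_derivatives <- function(expression, sample_times = NULL, epochs = NULL) {
  expression <- as.matrix(expression)
  m <- ncol(expression)
  if (m < 2L) stop("need at least two time samples")
  if (is.null(sample_times)) sample_times <- seq_len(m)
  sample_times <- as.numeric(sample_times)
  if (length(sample_times) != m) stop("sample_times must have length ncol(expression)")
  if (any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing (duplicates not allowed)")
  segs <- if (is.null(epochs)) list(seq_len(m)) else as_epoch_partition(epochs, m)
  D <- matrix(0, nrow(expression), m,
              dimnames = dimnames(expression))
  for (idx in segs) {
    if (length(idx) < 2L)
      stop("every epoch needs at least two samples to estimate derivatives")
    t_ <- sample_times[idx]
    x <- expression[, idx, drop = FALSE]
    mloc <- length(idx)
    d <- matrix(0, nrow(x), mloc)
    d[, 1] <- (x[, 2] - x[, 1]) / (t_[2] - t_[1])
    d[, mloc] <- (x[, mloc] - x[, mloc - 1]) / (t_[mloc] - t_[mloc - 1])
    if (mloc > 2L) {
      for (j in 2:(mloc - 1L))
        d[, j] <- (x[, j + 1] - x[, j - 1]) / (t_[j + 1] - t_[j - 1])
    }
    D[, idx] <- d
  }
  D
}

#' Normalize an epoch partition
#'
#' Accepts either a list of 1-based column-index vectors or an integer
#' vector of consecutive epoch lengths (e.g. `c(9, 9, 9, 8)`), and checks
#' that the epochs cover `1..m` disjointly.
#'
#' @param epochs list of index vectors or vector of lengths.
#' @param m total number of samples to cover.
#' @return List of integer index vectors.
#' @export
as_epoch_partition <- function(epochs, m) {
  if (!is.list(epochs)) {
    lens <- as.integer(epochs)
    if (any(lens < 1L)) stop("epoch lengths must be positive")
    ends <- cumsum(lens)
    epochs <- mapply(function(a, b) seq.int(a, b),
                     c(1L, utils::head(ends, -1L) + 1L), ends,
                     SIMPLIFY = FALSE)
  }
  epochs <- lapply(epochs, as.integer)
  if (any(vapply(epochs, length, 1L) == 0L)) stop("empty epoch in partition")
  flat <- unlist(epochs)
  if (anyDuplicated(flat)) stop("epoch partition has overlapping samples")
  if (!setequal(flat, seq_len(m)))
    stop("epoch partition must cover all ", m, " samples exactly")
  epochs
}
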