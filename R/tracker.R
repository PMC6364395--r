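#' Configuration for the sparse Kalman tracker
#'
#' @param alpha sparsity/fidelity tradeoff of the l1 projection, in `[0, 1]`
#'   (default 0.2, the value at which edge detection and reconstruction
#'   error balance in the synthetic study).
#' @param delta AKRON neighborhood size (default 1).
#' @param q_scale isotropic process-noise variance (default `1e-2`): how
#'   fast edges are allowed to drift between epochs.
#' @param r_scale isotropic observation-noise variance (default `1e-1`).
#' @param p0_scale initial covariance scale (default `1e2`); a diffuse prior
#'   on the unknown initial network.
#' @param smooth run the Rauch-Tung-Striebel backward pass and re-apply the
#'   projection and AKRON refinement to the smoothed estimates.
#' @param noise_eps nonnegative observation-noise threshold; positive values
#'   switch the refinement to the adaptive [akron_noisy()] rule.
#' @param zero_tol relative zero-counting tolerance handed to the solvers.
#' @param carry which estimate seeds the next epoch's prior mean:
#'   `"akron"` (default) keeps the refined sparse vector in the loop, so
#'   sparsity persists across epochs; `"l1"` carries the soft-thresholded
#'   estimate (the constrained Lasso-Kalman filter, the natural baseline the
#'   AKRON refinement is compared against); `"raw"` carries the plain
#'   Kalman posterior.
#' @return Object of class `"tracker_config"`.
#' @export
tracker_config <- function(alpha = 0.2, delta = 1L, q_scale = 1e-2,
                           r_scale = 1e-1, p0_scale = 1e2, smooth = FALSE,
                           noise_eps = 0, zero_tol = 1e-3,
                           carry = c("akron", "l1", "raw")) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (delta < 0) stop("delta must be nonnegative")
  stopifnot(q_scale >= 0, r_scale > 0, p0_scale > 0, noise_eps >= 0,
            zero_tol > 0)
  structure(list(alpha = alpha, delta = as.integer(delta), q_scale = q_scale,
                 r_scale = r_scale, p0_scale = p0_scale,
                 smooth = isTRUE(smooth), noise_eps = noise_eps,
                 zero_tol = zero_tol, carry = match.arg(carry)),
            class = "tracker_config")
}

# refine one estimate: l1-project, then AKRON against the epoch's system
refine_estimate <- function(a_est, X, y, config) {
  a_l1 <- lasso_project(a_est, config$alpha)
  sys <- underdetermined_system(t(X), y, noise_eps = config$noise_eps)
  seed <- sparse_solution(a_l1, sys,
                          zero_set = which(a_l1 == 0),
                          zero_tol = config$zero_tol)
  sol <- if (config$noise_eps > 0) {
    akron_noisy(sys, seed, zero_tol = config$zero_tol)
  } else {
    akron(sys, seed, delta = config$delta, zero_tol = config$zero_tol)
  }
  list(l1 = a_l1, akron = sol)
}

#' Track one gene's incoming-edge vector across epochs
#'
#' Runs the per-epoch cycle: predict under the random walk, update on the
#' epoch's stacked observations, project the posterior mean onto
#' approximately sparse vectors ([lasso_project()]), and refine the
#' projection with the AKRON search against the epoch's under-determined
#' system \eqn{\Phi = X^\top(k)}, \eqn{y = y_i(k)}. The refined sparse
#' vector is both the epoch's output and (with `carry = "akron"`) the prior
#' mean carried into the next epoch; the covariance always carries forward
#' from the standard update. With `config$smooth` the RTS backward pass runs
#' over the filtered (pre-projection) sequence and the projection plus
#' refinement are re-applied to each smoothed mean.
#'
#' @param epochs list with one element per epoch, each a list holding `X`
#'   (p x n_k expression matrix) and `y` (length-n_k rate-of-change vector
#'   for this gene). Every epoch must have `n_k < p`.
#' @param config a [tracker_config()].
#' @return List with per-epoch matrices/vectors: `raw`, `l1`, `akron` (lists
#'   of length-p vectors), `residuals` (AKRON residual per epoch), and when
#'   smoothing `raw_s`, `l1_s`, `akron_s`, `residuals_s`.
#' @export
track_gene <- function(epochs, config = tracker_config()) {
  stopifnot(inherits(config, "tracker_config"), length(epochs) >= 1L)
  p <- nrow(epochs[[1L]]$X)
  T_ <- length(epochs)
  for (e in epochs) {
    if (nrow(e$X) != p) stop("all epochs must share the gene dimension p")
    if (ncol(e$X) >= p)
      stop("each epoch needs n_k < p observations (the tracker targets ",
           "under-sampled epochs); got n_k = ", ncol(e$X), ", p = ", p)
    if (length(e$y) != ncol(e$X)) stop("epoch y must have length n_k")
  }
  state <- gene_state(numeric(p), diag(config$p0_scale, p), epoch = 0L)
  filtered <- predicted <- vector("list", T_)
  out <- list(raw = vector("list", T_), l1 = vector("list", T_),
              akron = vector("list", T_), residuals = numeric(T_))
  for (k in seq_len(T_)) {
    # the initial diffuse prior is the first prediction; afterwards inflate
    state <- if (k == 1L) state else kf_predict(state, config$q_scale)
    predicted[[k]] <- state
    post <- kf_update(state, epochs[[k]]$X, epochs[[k]]$y, config$r_scale)
    filtered[[k]] <- post
    ref <- refine_estimate(post$a, epochs[[k]]$X, epochs[[k]]$y, config)
    out$raw[[k]] <- post$a
    out$l1[[k]] <- ref$l1
    out$akron[[k]] <- ref$akron$x
    out$residuals[k] <- ref$akron$residual
    state <- post
    if (config$carry == "akron") state$a <- ref$akron$x
    else if (config$carry == "l1") state$a <- ref$l1
  }
  if (config$smooth) {
    sm <- rts_smooth(filtered, predicted)
    out$raw_s <- lapply(sm, `[[`, "a")
    out$l1_s <- vector("list", T_)
    out$akron_s <- vector("list", T_)
    out$residuals_s <- numeric(T_)
    for (k in seq_len(T_)) {
      ref <- refine_estimate(sm[[k]]$a, epochs[[k]]$X, epochs[[k]]$y, config)
      out$l1_s[[k]] <- ref$l1
      out$akron_s[[k]] <- ref$akron$x
      out$residuals_s[k] <- ref$akron$residual
    }
  }
  out
}

#' Track a full network from per-epoch observation matrices
#'
#' The workhorse behind [track_network()]: takes ready-made epoch data (one
#' `X` and one `Y` per epoch, with `Y` rows holding each gene's observed
#' rates of change) and runs [track_gene()] independently for every gene --
#' rows of the connectivity matrix are decoupled, so genes can be processed
#' in any order with identical results.
#'
#' @param epoch_data list with one element per epoch, each a list of `X`
#'   (p x n_k) and `Y` (p x n_k).
#' @param config a [tracker_config()].
#' @param gene_names optional length-p identifiers.
#' @return Object of class `"akron_networks"`: a list of per-method network
#'   sequences (`kf`, `l1`, `akron`, plus `kf_s`, `l1_s`, `akron_s` when
#'   smoothing), each a list of p x p matrices (row i = incoming edges of
#'   gene i), together with `gene_names`, `residuals` (genes x epochs), and
#'   the `config`.
#' @export
track_epochs <- function(epoch_data, config = tracker_config(),
                         gene_names = NULL) {
  stopifnot(length(epoch_data) >= 1L)
  p <- nrow(epoch_data[[1L]]$X)
  T_ <- length(epoch_data)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(p))
  if (length(gene_names) != p) stop("gene_names must have length p")
  methods <- c("kf", "l1", "akron")
  if (config$smooth) methods <- c(methods, "kf_s", "l1_s", "akron_s")
  nets <- lapply(methods, function(m)
    lapply(seq_len(T_), function(k)
      matrix(0, p, p, dimnames = list(gene_names, gene_names))))
  names(nets) <- methods
  residuals <- matrix(0, p, T_, dimnames = list(gene_names, NULL))
  key <- c(kf = "raw", l1 = "l1", akron = "akron",
           kf_s = "raw_s", l1_s = "l1_s", akron_s = "akron_s")
  for (i in seq_len(p)) {
    epochs_i <- lapply(epoch_data, function(e)
      list(X = e$X, y = as.numeric(e$Y[i, ])))
    tr <- track_gene(epochs_i, config)
    for (m in methods) {
      for (k in seq_len(T_)) nets[[m]][[k]][i, ] <- tr[[key[[m]]]][[k]]
    }
    residuals[i, ] <- tr$residuals
  }
  structure(c(nets, list(gene_names = gene_names, residuals = residuals,
                         config = config)),
            class = "akron_networks")
}

#' Infer a time-varying network from an expression matrix
#'
#' End-to-end driver: estimates expression rates of change by per-epoch
#' finite differences ([compute_derivatives()]), slices the expression
#' matrix into epochs, and tracks every gene's incoming-edge vector with
#' [track_gene()], assembling per-epoch connectivity matrices for the plain
#' Kalman filter, its l1 projection, and the AKRON refinement (and their
#' smoothed counterparts when requested).
#'
#' @param expression p x m numeric matrix, genes in rows.
#' @param epoch_partition epochs as accepted by [as_epoch_partition()]
#'   (index list or length vector, e.g. `c(9, 9, 9, 8)`).
#' @param config a [tracker_config()].
#' @param sample_times optional strictly increasing times of the m samples.
#' @param gene_names optional identifiers; defaults to `rownames(expression)`.
#' @return An `"akron_networks"` object; see [track_epochs()].
#' @export
track_network <- function(expression, epoch_partition,
                          config = tracker_config(), sample_times = NULL,
                          gene_names = NULL) {
  expression <- as.matrix(expression)
  if (is.null(gene_names)) gene_names <- rownames(expression)
  m <- ncol(expression)
  parts <- as_epoch_partition(epoch_partition, m)
  D <- compute_derivatives(expression, sample_times, parts)
  epoch_data <- lapply(parts, function(idx)
    list(X = expression[, idx, drop = FALSE], Y = D[, idx, drop = FALSE]))
  track_epochs(epoch_data, config, gene_names)
}

#' @export
print.akron_networks <- function(x, ...) {
  mth <- intersect(c("kf", "l1", "akron", "kf_s", "l1_s", "akron_s"), names(x))
  p <- length(x$gene_names)
  T_ <- length(x[[mth[1]]])
  cat(sprintf("Time-varying networks: %d genes, %d epochs\n", p, T_))
  cat("  methods:", paste(mth, collapse = ", "), "\n")
  nz <- vapply(x$akron, function(A) sum(A != 0), 1L)
  cat("  AKRON nonzero edges per epoch:", paste(nz, collapse = ", "), "\n")
  invisible(x)
}
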