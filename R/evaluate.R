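#' Binary edge support of a connectivity matrix
#'
#' @param A numeric matrix.
#' @param tol nonnegative threshold; an edge is present iff `|A_ij| > tol`
#'   (strict, so `tol = 0` keeps any nonzero entry).
#' @return Logical matrix of the same shape.
#' @export
edge_support <- function(A, tol = 0) {
  stopifnot(tol >= 0)
  abs(as.matrix(A)) > tol
}

#' Confusion counts of edge detection
#'
#' Tabulates an estimated edge-support matrix against a reference: positives
#' are edges present in the reference. All entries are scored, including the
#' diagonal, unless `mask_diagonal` drops self-loops.
#'
#' @param ref,est logical (or 0/1) matrices of equal shape, e.g. from
#'   [edge_support()]. For sequences of epochs, pass lists of matrices to
#'   accumulate counts across epochs.
#' @param mask_diagonal exclude self-loop entries from scoring.
#' @return Object of class `"confusion_counts"`: list with integer `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion <- function(ref, est, mask_diagonal = FALSE) {
  if (is.list(ref) || is.list(est)) {
    stopifnot(is.list(ref), is.list(est), length(ref) == length(est))
    parts <- mapply(confusion, ref, est,
                    MoreArgs = list(mask_diagonal = mask_diagonal),
                    SIMPLIFY = FALSE)
    out <- list(tp = sum(vapply(parts, `[[`, 1L, "tp")),
                tn = sum(vapply(parts, `[[`, 1L, "tn")),
                fp = sum(vapply(parts, `[[`, 1L, "fp")),
                fn = sum(vapply(parts, `[[`, 1L, "fn")))
    return(structure(out, class = "confusion_counts"))
  }
  ref <- as.matrix(ref) != 0
  est <- as.matrix(est) != 0
  if (!all(dim(ref) == dim(est))) stop("ref and est must have equal shape")
  if (mask_diagonal && nrow(ref) == ncol(ref)) {
    keep <- row(ref) != col(ref)
    ref <- ref[keep]; est <- est[keep]
  }
  structure(list(tp = sum(ref & est), tn = sum(!ref & !est),
                 fp = sum(!ref & est), fn = sum(ref & !est)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Edge confusion: TP %d  TN %d  FP %d  FN %d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Edge-detection summary statistics
#'
#' Accuracy, sensitivity, specificity and Matthews correlation coefficient
#' from confusion counts:
#' \deqn{acc = (TP+TN)/(TP+TN+FP+FN), \quad sen = TP/(TP+FN),}
#' \deqn{spe = TN/(TN+FP), \quad
#'   mcc = \frac{TP \cdot TN - FP \cdot FN}
#'              {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' A zero factor in the mcc denominator (and an empty denominator for sen or
#' spe) yields 0 by convention. The MCC is the balanced statistic of the
#' four: it only rewards predictors that beat the base rate on both classes,
#' which matters for sparse networks where negatives dominate.
#'
#' @param counts a `"confusion_counts"` object.
#' @param percent report acc/sen/spe/mcc multiplied by 100.
#' @return Named numeric vector `c(acc, sen, spe, mcc)`.
#' @export
edge_metrics <- function(counts, percent = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion counts")
  acc <- (tp + tn) / total
  sen <- if (tp + fn > 0) tp / (tp + fn) else 0
  spe <- if (tn + fp > 0) tn / (tn + fp) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  out <- c(acc = acc, sen = sen, spe = spe, mcc = mcc)
  if (percent) out * 100 else out
}

#' Squared-Frobenius reconstruction error of a network sequence
#'
#' \eqn{\sum_k \|A_{ref}(k) - A_{est}(k)\|_F^2} over aligned epoch
#' sequences (single matrices are treated as one-epoch sequences).
#'
#' @param ref,est numeric matrices or lists of matrices.
#' @return Nonnegative scalar.
#' @export
reconstruction_error <- function(ref, est) {
  if (!is.list(ref)) ref <- list(ref)
  if (!is.list(est)) est <- list(est)
  if (length(ref) != length(est)) stop("sequences must have equal length")
  tot <- 0
  for (k in seq_along(ref)) {
    A <- as.matrix(ref[[k]]); B <- as.matrix(est[[k]])
    if (!all(dim(A) == dim(B))) stop("matrix shapes differ at epoch ", k)
    tot <- tot + sum((A - B)^2)
  }
  tot
}
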