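## Benchmarking metrics for deconvolution results: per-type correlation with
## true proportions, root mean squared bias, goodness of fit of the
## reconstruction, reconstruction RMSE, and overlap with true cell-type
## markers derived from pure profiles.

#' Per-cell-type correlation with true proportions
#'
#' Pearson correlation across samples between matched rows of the estimated
#' and true proportion matrices.  Rows must already be aligned (see
#' [align_components()]); [evaluate_deconvolution()] performs the alignment.
#' A zero-variance row yields `NaN` with a warning.
#'
#' @param h_est,h_true Aligned K x N proportion matrices.
#' @return Numeric vector of length K.
#' @export
corr_with_true <- function(h_est, h_true) {
  h_est <- as.matrix(h_est); h_true <- as.matrix(h_true)
  if (!all(dim(h_est) == dim(h_true))) stop("shape mismatch")
  out <- vapply(seq_len(nrow(h_true)), function(k) {
    if (sd(h_est[k, ]) == 0 || sd(h_true[k, ]) == 0) {
      warning("zero-variance proportion row ", k, "; correlation is NaN")
      return(NaN)
    }
    cor(h_est[k, ], h_true[k, ])
  }, numeric(1))
  names(out) <- rownames(h_true)
  out
}

#' Root mean squared bias between estimated and true proportions
#'
#' \deqn{\mathrm{RMSBias} = \sqrt{\sum (H - \hat H)^2 / (KN)}}
#'
#' @param h_est,h_true Aligned K x N proportion matrices.
#' @return Non-negative scalar.
#' @export
rms_bias <- function(h_est, h_true) {
  h_est <- as.matrix(h_est); h_true <- as.matrix(h_true)
  if (!all(dim(h_est) == dim(h_true))) stop("shape mismatch")
  sqrt(sum((h_true - h_est)^2) / length(h_true))
}

#' Goodness of fit of a factorization
#'
#' Pearson correlation between the vectorized observed matrix and its
#' reconstruction \eqn{\hat Y = W H}.  Useful when true proportions are
#' unknown; constant observed data yields `NaN` with a warning.
#'
#' @param y Observed matrix (features x samples).
#' @param w Signature matrix (features x cell types).
#' @param h Proportion matrix (cell types x samples).
#' @return Scalar in \[-1, 1\].
#' @export
goodness_of_fit <- function(y, w, h) {
  y <- as.matrix(y)
  yhat <- as.matrix(w) %*% as.matrix(h)
  if (!all(dim(y) == dim(yhat))) stop("shape mismatch")
  if (sd(as.vector(y)) == 0 || sd(as.vector(yhat)) == 0) {
    warning("constant matrix; goodness of fit is NaN")
    return(NaN)
  }
  cor(as.vector(y), as.vector(yhat))
}

#' Reconstruction root mean squared error
#'
#' \deqn{\mathrm{RMSE} = \sqrt{\sum (Y - WH)^2 / (PN)}} computed over the
#' feature subset in `y`.  This is the quantity minimized across iterations
#' to pick the reported endpoint of [decomix()].
#'
#' @inheritParams goodness_of_fit
#' @return Non-negative scalar.
#' @export
model_rmse <- function(y, w, h) {
  y <- as.matrix(y)
  yhat <- as.matrix(w) %*% as.matrix(h)
  if (!all(dim(y) == dim(yhat))) stop("shape mismatch")
  sqrt(sum((y - yhat)^2) / length(y))
}

#' Derive true cell-type-specific markers from pure profiles
#'
#' Given per-cell-type mean profiles of pure cell types, scores each feature
#' for each cell type by the absolute log fold change of its level in that
#' type against the mean level of the other types (expression), or by the
#' absolute difference of means (methylation, where beta values near 0 make
#' the log unstable); absolute scores cover markers that are specifically low
#' as well as specifically high.  Each feature is attributed to the cell type
#' where its score is largest; per type, the top `ceiling(n / K)` attributed
#' features are pooled, the union is trimmed to `n` by score if too large and
#' topped up by the best remaining scores if too small.
#'
#' @param pure_means P x K matrix of per-cell-type mean profiles (features x
#'   cell types).
#' @param n Number of markers to return.
#' @param modality `"expression"` (log fold change scoring; requires strictly
#'   positive means) or `"methylation"` (mean-difference scoring).
#' @return Character vector of marker feature IDs.
#' @export
true_cts_markers <- function(pure_means, n,
                             modality = c("expression", "methylation")) {
  modality <- match.arg(modality)
  pure_means <- as.matrix(pure_means)
  p <- nrow(pure_means); kk <- ncol(pure_means)
  ids <- rownames(pure_means) %||% as.character(seq_len(p))
  if (kk < 2L) stop("need at least two cell types")
  score <- matrix(0, p, kk)
  for (k in seq_len(kk)) {
    others <- rowMeans(pure_means[, -k, drop = FALSE])
    if (modality == "expression") {
      if (any(pure_means[, k] <= 0) || any(others <= 0))
        stop("non-positive means under log fold-change scoring; ",
             "add an offset or use the methylation scoring")
      score[, k] <- abs(log(pure_means[, k]) - log(others))
    } else {
      score[, k] <- abs(pure_means[, k] - others)
    }
  }
  if (n >= p) return(ids)
  best <- apply(score, 1L, max)
  primary <- max.col(score, ties.method = "first")
  per_type <- ceiling(n / kk)
  sel <- unlist(lapply(seq_len(kk), function(k) {
    cand <- which(primary == k)
    cand[order(-score[cand, k], ids[cand])][seq_len(min(per_type,
                                                        length(cand)))]
  }))
  if (length(sel) > n) {
    sel <- sel[order(-best[sel], ids[sel])][seq_len(n)]
  } else if (length(sel) < n) {
    rest <- setdiff(seq_len(p), sel)
    extra <- rest[order(-best[rest], ids[rest])][seq_len(n - length(sel))]
    sel <- c(sel, extra)
  }
  ids[sel]
}

#' Overlap between two feature sets
#'
#' @param a,b Character vectors of feature IDs.
#' @return Integer: the size of the intersection.
#' @export
marker_overlap <- function(a, b) length(intersect(a, b))

#' Full evaluation of a deconvolution result against ground truth
#'
#' Aligns the estimated components to the truth ([align_components()]), then
#' computes per-type and mean correlation with the true proportions, the root
#' mean squared bias, and — when `y` and `w` are supplied — the goodness of
#' fit and reconstruction RMSE; optionally the overlap between selected and
#' true marker sets.
#'
#' @param h_est Estimated K x N proportion matrix (unaligned).
#' @param h_true True K x N proportion matrix.
#' @param y,w Optional observed submatrix and matching signature for the
#'   fit-based metrics (the proportions used are the aligned `h_est`).
#' @param markers_est,markers_true Optional feature-ID vectors for the marker
#'   overlap count.
#' @return An object of class `"decomix_eval"`: list with `alignment`,
#'   `per_type_correlation`, `mean_correlation`, `rms_bias`, and optionally
#'   `goodness_of_fit`, `model_rmse`, `marker_overlap`.  `NaN` correlations
#'   (zero-variance rows) are dropped from the mean with a message.
#' @export
evaluate_deconvolution <- function(h_est, h_true, y = NULL, w = NULL,
                                   markers_est = NULL, markers_true = NULL) {
  perm <- align_components(h_est, h_true)
  ha <- as.matrix(h_est)[perm, , drop = FALSE]
  ctc <- corr_with_true(ha, h_true)
  if (anyNA(ctc))
    message(sum(is.na(ctc)), " zero-variance component(s) excluded from the mean")
  out <- list(alignment = perm, per_type_correlation = ctc,
              mean_correlation = mean(ctc, na.rm = TRUE),
              rms_bias = rms_bias(ha, h_true))
  if (!is.null(y) && !is.null(w)) {
    out$goodness_of_fit <- goodness_of_fit(y, w, h_est)
    out$model_rmse <- model_rmse(y, w, h_est)
  }
  if (!is.null(markers_est) && !is.null(markers_true))
    out$marker_overlap <- marker_overlap(markers_est, markers_true)
  class(out) <- "decomix_eval"
  out
}

#' @export
print.decomix_eval <- function(x, ...) {
  cat("metric\tvalue\n")
  for (k in seq_along(x$per_type_correlation))
    cat(sprintf("corr_%s\t%.6g\n",
                names(x$per_type_correlation)[k] %||% k,
                x$per_type_correlation[k]))
  cat(sprintf("mean_correlation\t%.6g\n", x$mean_correlation))
  cat(sprintf("rms_bias\t%.6g\n", x$rms_bias))
  if (!is.null(x$goodness_of_fit))
    cat(sprintf("goodness_of_fit\t%.6g\n", x$goodness_of_fit))
  if (!is.null(x$model_rmse))
    cat(sprintf("model_rmse\t%.6g\n", x$model_rmse))
  if (!is.null(x$marker_overlap))
    cat(sprintf("marker_overlap\t%d\n", x$marker_overlap))
  invisible(x)
}
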