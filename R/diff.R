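## Cross-cell-type differential analysis from mixed samples.  With estimated
## proportions theta_s for sample s, the observed feature values follow
##   E(Y_p) = V beta_p,   V[s, k] = theta_sk,
## so the OLS coefficient beta_pk estimates the mean level of feature p in
## cell type k.  Cell-type-specific features are found by testing the
## one-vs-rest contrast mu_pk - mean(mu_p,-k) = 0 with a Wald t statistic
## whose residual variance is stabilized by a data-driven lower bound.

#' Fit per-feature cell-type means from mixed samples
#'
#' Regresses every feature of `y` on the proportion-valued design
#' `V = t(h)` by ordinary least squares, yielding estimated mean levels per
#' cell type, and stabilizes the per-feature residual variances with the
#' data-driven floor of [variance_floor()].
#'
#' @param y Mixture matrix (features x samples), analysed on the scale the
#'   linear model is assumed on (linear intensities, beta values, or
#'   log2-normalized counts for RNA-seq).
#' @param h Proportion matrix (cell types x samples); columns must sum to 1
#'   within 1e-8 and `V` must have full column rank.
#' @param floor_quantile Quantile of the residual-variance distribution used
#'   as the lower bound (default 0.10).
#' @return An object of class `"ct_fit"`: list with `beta` (P x K matrix of
#'   estimated cell-type means), `sigma2_raw`, `sigma2_floored`,
#'   `floor_value`, `df` (`N - K`), and the design `V`.
#' @export
fit_celltype_means <- function(y, h, floor_quantile = 0.10) {
  y <- as.matrix(y); h <- as.matrix(h)
  if (ncol(y) != ncol(h))
    stop("y and h disagree on the number of samples")
  if (anyNA(y) || anyNA(h)) stop("NA/NaN values are not allowed")
  n <- ncol(y); k <- nrow(h)
  if (n <= k) stop("insufficient degrees of freedom: need more samples (",
                   n, ") than cell types (", k, ")")
  cs <- colSums(h)
  if (any(abs(cs - 1) > 1e-8))
    stop("proportion columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  v <- t(h)
  if (qr(v)$rank < k) stop("proportion design matrix is rank deficient")
  xtx <- crossprod(v)
  xtxinv <- chol2inv(chol(xtx))
  beta <- y %*% v %*% xtxinv                 # P x K
  colnames(beta) <- rownames(h) %||% paste0("C", seq_len(k))
  res <- y - beta %*% t(v)
  sigma2_raw <- rowSums(res^2) / (n - k)
  fl <- variance_floor(sigma2_raw, q = floor_quantile)
  out <- list(beta = beta, sigma2_raw = sigma2_raw,
              sigma2_floored = fl$sigma2_floored, floor_value = fl$floor_value,
              df = n - k, V = v, XtXinv = xtxinv,
              celltypes = rownames(h) %||% paste0("C", seq_len(k)),
              features = rownames(y) %||% as.character(seq_len(nrow(y))))
  class(out) <- "ct_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ct_fit <- function(x, ...) {
  cat("Cell-type means fit:", nrow(x$beta), "features x", ncol(x$beta),
      "cell types, df =", x$df, "\n")
  cat("  variance floor:", format(x$floor_value, digits = 6), "(",
      sum(x$sigma2_raw < x$floor_value), "features floored )\n")
  invisible(x)
}

#' Data-driven lower bound on residual variances
#'
#' Extremely small residual-variance estimates inflate test statistics; they
#' are stabilized by flooring all per-feature variances at an empirical
#' quantile (default the 10th percentile) of the variance distribution.  The
#' quantile uses the linear-interpolation convention
#' (`quantile(..., type = 7)`, under which the 0.1 quantile of 1..10 is 1.9).
#' If the quantile is exactly zero, an epsilon fallback of
#' `1e-12 * max(1, max(sigma2))` is used instead.
#'
#' @param sigma2 Non-negative numeric vector of raw residual variances.
#' @param q Quantile level in \[0, 1\] (default 0.10).
#' @return List with `sigma2_floored` and `floor_value`.
#' @export
variance_floor <- function(sigma2, q = 0.10) {
  if (length(sigma2) < 1L) stop("need at least one variance")
  if (any(sigma2 < 0)) stop("negative variances are not allowed")
  fl <- unname(quantile(sigma2, probs = q, type = 7))
  if (fl == 0) fl <- 1e-12 * max(1, max(sigma2))
  list(sigma2_floored = pmax(sigma2, fl), floor_value = fl)
}

#' Clamp negative estimated cell-type means at zero
#'
#' The coefficients of the proportion-design model represent mean observation
#' levels and are not physically negative; this optional post-hoc step clamps
#' negative estimates to zero before contrast testing.  Residual variances are
#' not recomputed.
#'
#' @param fit A `"ct_fit"` object.
#' @param enabled Apply the clamp (default `FALSE`, as negative estimates are
#'   typically rare and have little impact).
#' @return The (possibly modified) `"ct_fit"`; the fraction of clamped
#'   entries is reported via `message()` when `enabled` is `TRUE`.
#' @export
bound_negative_means <- function(fit, enabled = FALSE) {
  stopifnot(inherits(fit, "ct_fit"))
  if (!enabled) return(fit)
  neg <- fit$beta < 0
  frac <- mean(neg)
  message("bound_negative_means: clamped ", sum(neg), " of ", length(neg),
          " coefficients (", format(100 * frac, digits = 3), "%)")
  fit$beta[neg] <- 0
  fit
}

#' Test one cell type against the average of the others
#'
#' For cell type `k`, tests per feature the contrast
#' \deqn{H_0:\; \mu_{pk} - \frac{1}{K-1}\sum_{i \ne k} \mu_{pi} = 0}
#' with a Wald t statistic: the contrast estimate divided by its standard
#' error computed from the floored residual variance, referred to a
#' Student-t distribution with `N - K` degrees of freedom (two-sided).
#'
#' @param fit A `"ct_fit"` object from [fit_celltype_means()].
#' @param k Cell-type index (or label) to test against the rest.
#' @return A data.frame with columns `feature`, `celltype`, `estimate`, `se`,
#'   `statistic`, `p_value`.
#' @export
test_celltype_contrast <- function(fit, k) {
  stopifnot(inherits(fit, "ct_fit"))
  kk <- ncol(fit$beta)
  if (kk < 2L) stop("contrast undefined for a single cell type")
  if (is.character(k)) k <- match(k, fit$celltypes)
  if (is.na(k) || k < 1L || k > kk) stop("invalid cell-type index")
  cvec <- rep(-1 / (kk - 1L), kk)
  cvec[k] <- 1
  est <- drop(fit$beta %*% cvec)
  cf <- drop(crossprod(cvec, fit$XtXinv %*% cvec))
  se <- sqrt(fit$sigma2_floored * cf)
  stat <- est / se
  p <- 2 * pt(-abs(stat), df = fit$df)
  data.frame(feature = fit$features, celltype = fit$celltypes[k],
             estimate = est, se = se, statistic = stat, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-cell-type differential analysis for all cell types
#'
#' Runs [test_celltype_contrast()] for every cell type and collects the
#' results as P x K matrices, the form consumed by [select_markers()].
#'
#' @param fit A `"ct_fit"` object.
#' @return An object of class `"crosscell_diff"`: list of P x K matrices
#'   `estimate`, `se`, `statistic`, `p_value` (rows = features, columns =
#'   cell types), plus the originating `fit`.
#' @export
crosscell_test <- function(fit) {
  stopifnot(inherits(fit, "ct_fit"))
  kk <- ncol(fit$beta)
  if (kk < 2L) stop("contrast undefined for a single cell type")
  cols <- lapply(seq_len(kk), function(k) test_celltype_contrast(fit, k))
  grab <- function(field) {
    m <- vapply(cols, function(d) d[[field]], numeric(nrow(fit$beta)))
    dimnames(m) <- list(fit$features, fit$celltypes)
    m
  }
  out <- list(estimate = grab("estimate"), se = grab("se"),
              statistic = grab("statistic"), p_value = grab("p_value"),
              fit = fit)
  class(out) <- "crosscell_diff"
  out
}

#' @export
print.crosscell_diff <- function(x, ...) {
  cat("Cross-cell-type differential analysis:", nrow(x$p_value), "features x",
      ncol(x$p_value), "cell types\n")
  cat("  features with min p < 0.05:",
      sum(apply(x$p_value, 1L, min) < 0.05), "\n")
  invisible(x)
}

#' Serialize differential results to a long-format data.frame
#'
#' @param x A `"crosscell_diff"` object.
#' @param ... Unused.
#' @return A data.frame with columns `feature`, `celltype`, `estimate`, `se`,
#'   `statistic`, `p_value` (one row per feature x cell type), suitable for
#'   writing as TSV.
#' @export
as.data.frame.crosscell_diff <- function(x, ...) {
  kk <- ncol(x$p_value)
  do.call(rbind, lapply(seq_len(kk), function(k)
    data.frame(feature = rownames(x$p_value),
               celltype = colnames(x$p_value)[k],
               estimate = x$estimate[, k], se = x$se[, k],
               statistic = x$statistic[, k], p_value = x$p_value[, k],
               row.names = NULL, stringsAsFactors = FALSE)))
}
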