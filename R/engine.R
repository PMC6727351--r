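## Reference-free deconvolution engine: alternating constrained least squares
## for Y ~ W H with H columns on the unit simplex and W non-negative
## (additionally bounded by 1 for methylation).  The per-sample and
## per-feature subproblems are solved exactly by compiled active-set solvers.

#' Estimate mixing proportions given a signature matrix
#'
#' Solves, for every sample s, the simplex-constrained least-squares problem
#' \deqn{\hat h_s = \arg\min_h \|y_s - W h\|^2 \quad \mathrm{s.t.}\; h \ge 0,\;
#' \textstyle\sum_k h_k = 1,} i.e. the proportion half-step of the alternating
#' factorization.  Solutions are exact (active-set quadratic programming), and
#' returned columns are renormalized to sum to one exactly.
#'
#' @param y Numeric matrix (features x samples) restricted to the signature
#'   features.
#' @param w Signature matrix (features x cell types), non-negative.
#' @return A K x N proportion matrix; rownames are the cell-type labels of
#'   `w`, colnames the sample IDs of `y`.
#' @export
update_proportions <- function(y, w) {
  y <- as.matrix(y); w <- as.matrix(w)
  if (nrow(y) != nrow(w))
    stop("dimension mismatch: y has ", nrow(y), " features, w has ", nrow(w))
  if (anyNA(y) || anyNA(w)) stop("NA/NaN values are not allowed")
  if (qr(w)$rank < ncol(w))
    warning("signature matrix is not of full column rank; ",
            "proportions may not be uniquely determined")
  h <- cpp_simplex_ls(w, y)
  h <- sweep(h, 2L, colSums(h), "/")
  dimnames(h) <- list(colnames(w), colnames(y))
  h
}

#' Estimate the signature matrix given proportions
#'
#' Solves, for every feature p, the bound-constrained least-squares problem
#' \eqn{\hat w_p = \arg\min_w \|y_p - H^T w\|^2} subject to \eqn{w \ge 0}
#' (and \eqn{w \le 1} for methylation), i.e. the signature half-step of the
#' alternating factorization.
#'
#' @param y Numeric matrix (features x samples).
#' @param h Proportion matrix (cell types x samples); columns must lie on the
#'   unit simplex.
#' @param modality `"expression"` or `"methylation"`; methylation bounds the
#'   signature entries by 1.
#' @return A features x cell-types signature matrix.
#' @export
update_signature <- function(y, h, modality = c("expression", "methylation")) {
  modality <- match.arg(modality)
  y <- as.matrix(y); h <- as.matrix(h)
  if (ncol(y) != ncol(h))
    stop("dimension mismatch: y has ", ncol(y), " samples, h has ", ncol(h))
  if (anyNA(y) || anyNA(h)) stop("NA/NaN values are not allowed")
  upper <- if (modality == "methylation") 1 else Inf
  w <- cpp_box_ls(h, y, upper)
  dimnames(w) <- list(rownames(y), rownames(h))
  w
}

#' Reference-free deconvolution by alternating constrained least squares
#'
#' Factorizes `y` as `W H` with non-negative signatures and simplex-constrained
#' proportion columns, alternating exact constrained least-squares updates of
#' `H` (per sample) and `W` (per feature) from random starts.  The Frobenius
#' objective is non-increasing across inner iterations; among restarts the
#' solution with the smallest reconstruction RMSE is kept.  Components are
#' unlabeled: rows of `H` come back as `C1..CK` and must be aligned to any
#' ground truth with [align_components()] before comparison.
#'
#' @param y Numeric matrix (features x samples), typically restricted to a
#'   candidate marker set.
#' @param k Number of cell types (`k = 1` is handled analytically).
#' @param modality `"expression"` or `"methylation"`.
#' @param seed Integer seed; restart `r` uses `seed + r`, so the fit is fully
#'   reproducible.
#' @param n_restarts Number of random restarts (default 3).
#' @param tol Relative decrease of the Frobenius objective below which the
#'   inner loop stops (default 1e-6).
#' @param max_inner Cap on inner alternations (default 1000).
#' @return An object of class `"deconv_fit"`: list with elements `W`
#'   (signature), `H` (proportions), `rmse` (reconstruction RMSE
#'   \eqn{\sqrt{\sum (Y - WH)^2 / (MN)}}), `n_restarts_used`, and `converged`.
#' @examples
#' set.seed(1)
#' w <- matrix(runif(40), 20, 2)
#' h <- matrix(c(0.3, 0.7, 0.6, 0.4, 0.5, 0.5), 2, 3)
#' fit <- rf_deconvolve(w %*% h, k = 2, seed = 1)
#' fit$rmse
#' @export
rf_deconvolve <- function(y, k, modality = c("expression", "methylation"),
                          seed = 1L, n_restarts = 3L, tol = 1e-6,
                          max_inner = 1000L) {
  modality <- match.arg(modality)
  y <- as.matrix(y)
  if (anyNA(y)) stop("y contains NA/NaN values")
  m <- nrow(y); n <- ncol(y)
  if (k < 1L) stop("k must be at least 1")
  if (k == 1L) {
    w <- matrix(rowMeans(y), m, 1L, dimnames = list(rownames(y), "C1"))
    h <- matrix(1, 1L, n, dimnames = list("C1", colnames(y)))
    out <- list(W = w, H = h, rmse = sqrt(sum((y - w %*% h)^2) / (m * n)),
                n_restarts_used = 0L, converged = TRUE)
    class(out) <- "deconv_fit"
    return(out)
  }
  if (k > min(m, n))
    stop("k = ", k, " exceeds min(features, samples) = ", min(m, n))
  if (all(abs(y - y[1L]) < 1e-12))
    stop("y is constant; no separable structure to deconvolve")

  upper <- if (modality == "methylation") 1 else Inf
  ymax <- max(y)
  if (modality == "methylation") ymax <- min(1, max(ymax, .Machine$double.eps))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    w0 <- matrix(runif(m * k, 0, ymax), m, k)
    g <- matrix(rgamma(k * n, shape = 1), k, n)
    h0 <- sweep(g, 2L, colSums(g), "/")
    fit <- cpp_als(y, w0, h0, upper, tol, as.integer(max_inner))
    obj <- fit$objective
    if (length(obj) > 1L && any(diff(obj) > 1e-8 * max(abs(obj[1L]), 1)))
      warning("objective increased during alternation (restart ", r, ")")
    h <- sweep(fit$H, 2L, colSums(fit$H), "/")
    if (any(apply(h, 1L, max) < 1e-6)) next     # degenerate component
    rmse <- sqrt(obj[length(obj)] / (m * n))
    if (is.null(best) || rmse < best$rmse)
      best <- list(W = fit$W, H = h, rmse = rmse, converged = fit$converged,
                   objective = obj)
  }
  if (is.null(best))
    stop("all ", n_restarts, " restarts produced a degenerate component; ",
         "consider lowering k")
  dimnames(best$W) <- list(rownames(y), paste0("C", seq_len(k)))
  dimnames(best$H) <- list(paste0("C", seq_len(k)), colnames(y))
  out <- list(W = best$W, H = best$H, rmse = best$rmse,
              n_restarts_used = as.integer(n_restarts),
              converged = best$converged, objective = best$objective)
  class(out) <- "deconv_fit"
  out
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat("Reference-free deconvolution fit\n")
  cat("  features:", nrow(x$W), " samples:", ncol(x$H),
      " cell types:", ncol(x$W), "\n")
  cat("  reconstruction RMSE:", format(x$rmse, digits = 6),
      if (isTRUE(x$converged)) "(converged)\n" else "(iteration cap)\n")
  invisible(x)
}

#' Reference-based proportion estimation
#'
#' Estimates mixing proportions by constrained least squares against a known
#' signature matrix of purified cell-type profiles: for each sample the
#' proportions minimize the residual sum of squares subject to non-negativity
#' and sum-to-one.  Features are matched by rowname between `y` and `w_ref`.
#'
#' @param y Mixture matrix (features x samples).
#' @param w_ref Reference signature matrix (features x cell types).
#' @return A K x N proportion matrix with the reference cell-type labels.
#' @export
reference_based_estimate <- function(y, w_ref) {
  y <- as.matrix(y); w_ref <- as.matrix(w_ref)
  common <- intersect(rownames(y), rownames(w_ref))
  if (length(common) < ncol(w_ref))
    stop("only ", length(common), " reference features found in y; need at least ",
         ncol(w_ref))
  update_proportions(y[common, , drop = FALSE], w_ref[common, , drop = FALSE])
}

#' Align unlabeled components to a reference ordering
#'
#' Reference-free components come back in arbitrary order (label switching).
#' This finds the permutation `perm` maximizing the sum over cell types of the
#' Pearson correlation between `h_est[perm[j], ]` and `h_true[j, ]`, by exact
#' search over all assignments.  Zero-variance rows contribute correlation 0.
#' Ties are broken by the lexicographically smallest permutation.
#'
#' @param h_est,h_true K x N proportion matrices.
#' @return An integer permutation of `1:K` such that
#'   `h_est[align_components(h_est, h_true), ]` matches `h_true` row for row.
#' @export
align_components <- function(h_est, h_true) {
  h_est <- as.matrix(h_est); h_true <- as.matrix(h_true)
  k <- nrow(h_true)
  if (nrow(h_est) != k)
    stop("component count mismatch: ", nrow(h_est), " vs ", k)
  if (ncol(h_est) != ncol(h_true)) stop("sample count mismatch")
  if (k == 1L) return(1L)
  if (k > 9L) stop("alignment supported for at most 9 components")
  cc <- matrix(0, k, k)       # cc[i, j] = cor(est row i, true row j)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (sd(h_est[i, ]) == 0 || sd(h_true[j, ]) == 0) next
    cc[i, j] <- cor(h_est[i, ], h_true[j, ])
  }
  perms <- permutations_lex(k)
  best <- perms[[1L]]
  best_s <- sum(cc[cbind(best, seq_len(k))])
  for (p in perms[-1L]) {
    s <- sum(cc[cbind(p, seq_len(k))])
    if (s > best_s + 1e-12) { best <- p; best_s <- s }
  }
  best
}

## All permutations of 1..k in lexicographic order.
permutations_lex <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (p in permutations_lex(k - 1L))
      out[[length(out) + 1L]] <- c(first, rest[p])
  }
  out
}
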