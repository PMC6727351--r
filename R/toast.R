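## The iterative feature-selection / deconvolution loop: start from an initial
## feature set, deconvolve, re-detect cell-type-specific features on the whole
## matrix using the estimated proportions, re-deconvolve on the new set, and
## finally report the iteration with the smallest reconstruction RMSE.

#' Select an initial feature set
#'
#' Two conventional strategies: a window of the variance ranking (features
#' ranked by row variance, descending; `window = c(lo, hi)` returns ranks
#' `lo..hi`), or a seeded uniform random sample of `n_marker` features.  The
#' default window 1001–2000 skips the most variable features, whose variance
#' is often dominated by within-cell-type noise rather than cross-cell-type
#' differences.
#'
#' @param y Mixture matrix (features x samples).
#' @param method `"variance"` or `"random"`.
#' @param window Integer pair `c(lo, hi)` of variance ranks (variance method).
#' @param n_marker Number of features for the random method (default 1000).
#' @param seed Seed for the random method.
#' @param k Optional number of cell types, used to validate that the set is
#'   large enough.
#' @return Character vector of selected feature IDs (ordered by rank or draw).
#' @export
initial_features <- function(y, method = c("variance", "random"),
                             window = c(1001L, 2000L), n_marker = 1000L,
                             seed = 1L, k = NULL) {
  method <- match.arg(method)
  y <- as.matrix(y)
  p <- nrow(y)
  ids <- rownames(y) %||% as.character(seq_len(p))
  if (method == "variance") {
    lo <- as.integer(window[1L]); hi <- as.integer(window[2L])
    if (lo < 1L || hi < lo) stop("invalid variance window")
    if (hi > p) stop("variance window (", lo, "-", hi,
                     ") exceeds the number of features (", p, ")")
    if (!is.null(k) && hi - lo + 1L < k)
      stop("window smaller than the number of cell types")
    rv <- rowSums((y - rowMeans(y))^2) / (ncol(y) - 1L)
    sel <- order(-rv)[lo:hi]         # stable: ties broken by feature order
  } else {
    n_marker <- as.integer(n_marker)
    if (n_marker > p) stop("n_marker (", n_marker,
                           ") exceeds the number of features (", p, ")")
    if (!is.null(k) && n_marker < k)
      stop("n_marker must be at least the number of cell types")
    set.seed(seed)
    sel <- sample.int(p, n_marker)
  }
  ids[sel]
}

#' Select candidate markers from differential results
#'
#' Builds the next feature set from a cross-cell-type differential analysis:
#' within each cell type, features are ranked by ascending p-value (ties by
#' descending absolute contrast estimate, then by feature ID), and the
#' per-type rankings are merged round-robin in cell-type order — each round
#' takes the next not-yet-selected feature from each type — until `n_marker`
#' unique features are collected (or all features are exhausted).
#'
#' @param diff A `"crosscell_diff"` object from [crosscell_test()].
#' @param n_marker Number of features to select (default 1000).
#' @return Character vector of selected feature IDs, in selection order.
#' @export
select_markers <- function(diff, n_marker = 1000L) {
  stopifnot(inherits(diff, "crosscell_diff"))
  p <- nrow(diff$p_value); kk <- ncol(diff$p_value)
  if (n_marker < kk) stop("n_marker must be at least the number of cell types")
  ids <- rownames(diff$p_value)
  rankings <- lapply(seq_len(kk), function(k)
    order(diff$p_value[, k], -abs(diff$estimate[, k]), ids))
  n_marker <- min(as.integer(n_marker), p)
  selected <- integer(0)
  taken <- logical(p)
  pos <- rep(1L, kk)                      # next rank to inspect per type
  while (length(selected) < n_marker) {
    progressed <- FALSE
    for (k in seq_len(kk)) {
      while (pos[k] <= p && taken[rankings[[k]][pos[k]]])
        pos[k] <- pos[k] + 1L
      if (pos[k] > p) next
      f <- rankings[[k]][pos[k]]
      taken[f] <- TRUE
      selected <- c(selected, f)
      pos[k] <- pos[k] + 1L
      progressed <- TRUE
      if (length(selected) >= n_marker) break
    }
    if (!progressed) break
  }
  ids[selected]
}

## Parse an init specification string like "variance:1001-2000" or
## "random:1000" into the arguments of initial_features().
parse_init <- function(init) {
  if (is.list(init)) return(init)
  parts <- strsplit(init, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("invalid init specification: ", init)
  if (parts[1L] == "variance") {
    w <- as.integer(strsplit(parts[2L], "-", fixed = TRUE)[[1L]])
    if (length(w) != 2L || anyNA(w)) stop("invalid variance window: ", init)
    list(method = "variance", window = w)
  } else if (parts[1L] == "random") {
    n <- as.integer(parts[2L])
    if (is.na(n)) stop("invalid random count: ", init)
    list(method = "random", n_marker = n)
  } else stop("unknown init method: ", parts[1L])
}

#' Reference-free deconvolution with iterative marker selection
#'
#' The main fitting function.  Starting from an initial feature set, it
#' alternates (i) reference-free deconvolution ([rf_deconvolve()]) on the
#' current feature subset and (ii) cross-cell-type differential analysis
#' ([fit_celltype_means()], [crosscell_test()]) on the *whole* matrix using
#' the latest proportion estimates, selecting the top `n_markers` features
#' ([select_markers()]) for the next round.  After `max_iter` iterations the
#' iteration with the smallest reconstruction RMSE (among iterations
#' `1..max_iter`; iteration 0 is the un-iterated baseline) is reported.
#'
#' @param y Mixture matrix (features x samples); rownames are feature IDs.
#' @param k Number of cell types (at least 2).
#' @param modality `"expression"` or `"methylation"`.
#' @param n_markers Number of features selected per iteration (default 1000).
#' @param max_iter Number of refinement iterations (default 30; more may be
#'   needed for small samples or many cell types).
#' @param init Initial feature selection, `"variance:LO-HI"` (default
#'   `"variance:1001-2000"`) or `"random:N"`.
#' @param seed Integer seed; iteration `t` re-seeds the engine with
#'   `seed + 1000 * t`, making the full trace reproducible.
#' @param restarts,tol,max_inner Engine options passed to [rf_deconvolve()].
#' @param bound_negative Clamp negative estimated cell-type means before
#'   contrast testing (default `FALSE`).
#' @param keep_iterations Keep the fitted signature matrix of every iteration
#'   (default keeps only proportions and feature sets; the chosen iteration's
#'   signature is always kept).
#' @param verbose Log per-iteration RMSE via `message()`.
#' @return An object of class `"decomix"` with components `proportions`
#'   (K x N, the estimate at the chosen iteration), `signature`, `features`,
#'   `trace` (data.frame: `iteration`, `rmse`, `n_features`, `chosen`),
#'   `chosen_iteration`, per-iteration `H_list` and `features_list`, and the
#'   matched call.  Standard methods (`print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `plot`, `simulate`) are available.
#' @examples
#' sim <- simulate_expression_dataset(
#'   default_panel_params(500, 3, n_markers_per_type = 40, seed = 7),
#'   n = 40, alpha = c(1, 2, 1), seed = 7)
#' fit <- decomix(sim$mixture, k = 3, n_markers = 100, max_iter = 3,
#'                init = "variance:101-200", seed = 7)
#' fit
#' @export
decomix <- function(y, k, modality = c("expression", "methylation"),
                    n_markers = 1000L, max_iter = 30L,
                    init = "variance:1001-2000", seed = 1L, restarts = 3L,
                    tol = 1e-6, max_inner = 1000L, bound_negative = FALSE,
                    keep_iterations = FALSE, verbose = FALSE) {
  modality <- match.arg(modality)
  y <- validate_mixture(as.matrix(y), modality)
  if (is.null(rownames(y))) rownames(y) <- paste0("f", seq_len(nrow(y)))
  if (is.null(colnames(y))) colnames(y) <- paste0("s", seq_len(ncol(y)))
  if (k < 2L) stop("k must be at least 2")
  if (ncol(y) <= k)
    stop("need more samples than cell types for differential analysis")
  if (max_iter < 1L) stop("max_iter must be at least 1")
  ini <- parse_init(init)
  feats <- do.call(initial_features,
                   c(list(y = y, seed = seed, k = k), ini))

  engine <- function(fs, s)
    rf_deconvolve(y[fs, , drop = FALSE], k = k, modality = modality,
                  seed = s, n_restarts = restarts, tol = tol,
                  max_inner = max_inner)

  rmse <- numeric(max_iter + 1L)
  H_list <- vector("list", max_iter + 1L)
  W_list <- vector("list", max_iter + 1L)
  features_list <- vector("list", max_iter + 1L)

  record <- function(t, fs, fit) {
    rmse[t + 1L] <<- fit$rmse
    H_list[[t + 1L]] <<- fit$H
    W_list[[t + 1L]] <<- fit$W
    features_list[[t + 1L]] <<- fs
    if (verbose) message(sprintf("iteration %d: rmse = %.6g (%d features)",
                                 t, fit$rmse, length(fs)))
  }

  partial_trace <- function(t) {
    data.frame(iteration = 0:(t - 1L), rmse = rmse[seq_len(t)],
               n_features = lengths(features_list[seq_len(t)]), chosen = 0L)
  }

  fit0 <- engine(feats, seed)
  record(0L, feats, fit0)
  h_prev <- fit0$H
  for (t in seq_len(max_iter)) {
    res <- tryCatch({
      ctf <- fit_celltype_means(y, h_prev)
      ctf <- bound_negative_means(ctf, enabled = bound_negative)
      d <- crosscell_test(ctf)
      fs <- select_markers(d, n_marker = n_markers)
      list(fs = fs, fit = engine(fs, seed + 1000L * t))
    }, error = function(e)
      stop(errorCondition(
        paste0("iteration ", t, " failed: ", conditionMessage(e)),
        trace = partial_trace(t), class = c("decomix_iteration_error", "error"))))
    record(t, res$fs, res$fit)
    h_prev <- res$fit$H
  }

  chosen <- which.min(rmse[-1L])          # iteration 0 excluded; ties earliest
  trace <- data.frame(iteration = 0:max_iter, rmse = rmse,
                      n_features = lengths(features_list),
                      chosen = as.integer(0:max_iter == chosen))
  out <- list(
    proportions = H_list[[chosen + 1L]],
    signature = W_list[[chosen + 1L]],
    features = features_list[[chosen + 1L]],
    trace = trace, chosen_iteration = chosen, rmse = rmse[chosen + 1L],
    H_list = H_list, features_list = features_list,
    W_list = if (keep_iterations) W_list else NULL,
    y_chosen = y[features_list[[chosen + 1L]], , drop = FALSE],
    k = k, modality = modality, n_markers = n_markers, seed = seed,
    call = match.call())
  class(out) <- "decomix"
  out
}
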