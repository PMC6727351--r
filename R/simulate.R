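## Ground-truth simulators.  Pure-cell-type panels are drawn per subject: for
## expression, log-values are Normal(m_pk, s_pk) and exponentiated
## (log-normal linear-scale profiles); for methylation, beta values are
## Normal(m_pk, s_pk) clipped to [0, 1].  Panels are mixed on the linear
## scale by Dirichlet-distributed proportions and additive Gaussian
## measurement noise is added.  An RNA-seq variant generates negative-
## binomial counts with planted cell-type-specific differentially expressed
## genes.

#' Construct default pure-panel parameters
#'
#' Builds a per-feature, per-cell-type location/scale parameterization of the
#' pure panels with planted cell-type-specific markers.  Non-marker features
#' share a common baseline with a small cross-cell-type spread (`type_sd`);
#' each planted marker gets an `effect` shift of random sign in its own cell
#' type (a log-scale shift for expression, i.e. `exp(effect)`-fold up or
#' down; a beta shift for methylation).  Within-cell-type (between-subject)
#' scales are heterogeneous with an exponential tail, so a minority of
#' features are highly variable within a cell type — the structure that
#' contaminates variance-ranked feature selection in real data.
#'
#' @param p Number of features.
#' @param k Number of cell types.
#' @param n_markers_per_type Planted markers per cell type (default 50, a
#'   realistic few-percent marker fraction at a few thousand features).
#' @param effect Marker effect size: shift of the location parameter in the
#'   marker's own cell type (default 2 on the natural-log scale for
#'   expression; use ~0.4 for methylation beta shifts).
#' @param type_sd Standard deviation of the per-type baseline deviations for
#'   all features (default 0.1 for expression, 0.03 for methylation): real
#'   pure profiles differ a little between cell types genome-wide, but only
#'   markers differ strongly.
#' @param seed Integer seed.
#' @param modality `"expression"` or `"methylation"`.
#' @return An object of class `"panel_params"`: list with `mean` and `sd`
#'   (P x K matrices on the log scale for expression, beta scale for
#'   methylation), `marker_type` (integer vector, `NA` for non-markers),
#'   `modality`, and feature/cell-type labels.
#' @export
default_panel_params <- function(p, k, n_markers_per_type = 50L,
                                 effect = 2, type_sd = NULL, seed = 1L,
                                 modality = c("expression", "methylation")) {
  modality <- match.arg(modality)
  n_markers_per_type <- as.integer(n_markers_per_type)
  if (k * n_markers_per_type > p)
    stop("cannot plant ", k * n_markers_per_type, " markers in ", p, " features")
  if (is.null(type_sd))
    type_sd <- if (modality == "expression") 0.05 else 0.02
  set.seed(seed)
  ids <- paste0("g", seq_len(p))
  cts <- paste0("C", seq_len(k))
  if (modality == "expression") {
    base <- rnorm(p, mean = 5, sd = 1)
    m <- base + matrix(rnorm(p * k, 0, type_sd), p, k)
    # within-cell-type (between-subject) variability is heterogeneous with a
    # heavy tail: a minority of features vary a lot between subjects, which
    # is exactly what contaminates variance-ranked feature selection
    s_feat <- pmin(0.02 + stats::rexp(p, rate = 1 / 0.03), 0.2)
    s <- matrix(s_feat, p, k)
  } else {
    base <- pmin(pmax(rbeta(p, 0.5, 0.5), 0.03), 0.97)
    m <- pmin(pmax(base + matrix(rnorm(p * k, 0, type_sd), p, k), 0), 1)
    s_feat <- pmin(0.02 + stats::rexp(p, rate = 1 / 0.02), 0.15)
    s <- matrix(s_feat, p, k)
  }
  marker_type <- rep(NA_integer_, p)
  marker_feats <- sample.int(p, k * n_markers_per_type)
  marker_type[marker_feats] <- rep(seq_len(k), each = n_markers_per_type)
  # cell-identity markers are stably expressed within their type: low
  # between-subject variability, unlike the heavy-tailed background
  s[marker_feats, ] <- if (modality == "expression")
    runif(length(marker_feats), 0.02, 0.06) else
    runif(length(marker_feats), 0.01, 0.03)
  for (k0 in seq_len(k)) {
    idx <- which(marker_type == k0)
    dir <- sample(c(-1, 1), length(idx), replace = TRUE)
    if (modality == "expression") {
      m[idx, k0] <- m[idx, k0] + dir * effect
    } else {
      m[idx, k0] <- pmin(pmax(m[idx, k0] + dir * effect, 0), 1)
    }
  }
  dimnames(m) <- dimnames(s) <- list(ids, cts)
  out <- list(mean = m, sd = s, marker_type = marker_type,
              modality = modality, p = p, k = k,
              feature_ids = ids, celltypes = cts)
  class(out) <- "panel_params"
  out
}

#' Estimate panel parameters from purified replicate profiles
#'
#' Computes per-feature, per-cell-type location and scale parameters from
#' measured pure-cell-type replicates: sample mean and standard deviation of
#' the log values for expression (requires positive values), or of the beta
#' values for methylation.  Cell types with a single replicate get a pooled
#' default scale (the median of the computable scales) with a warning.
#'
#' @param pure Matrix of purified profiles (features x replicate samples).
#' @param celltypes Character vector assigning each column of `pure` to a
#'   cell type.
#' @param modality `"expression"` or `"methylation"`.
#' @return A `"panel_params"` object (without marker annotation).
#' @export
estimate_panel_params <- function(pure, celltypes,
                                  modality = c("expression", "methylation")) {
  modality <- match.arg(modality)
  pure <- as.matrix(pure)
  if (ncol(pure) != length(celltypes))
    stop("celltypes must label every column of pure")
  cts <- unique(celltypes)
  if (modality == "expression") {
    if (any(pure <= 0)) stop("expression profiles must be positive for log scale")
    pure <- log(pure)
  }
  p <- nrow(pure)
  m <- s <- matrix(NA_real_, p, length(cts),
                   dimnames = list(rownames(pure) %||% paste0("g", seq_len(p)),
                                   cts))
  singletons <- character(0)
  for (j in seq_along(cts)) {
    cols <- which(celltypes == cts[j])
    m[, j] <- rowMeans(pure[, cols, drop = FALSE])
    if (length(cols) > 1L) s[, j] <- apply(pure[, cols, drop = FALSE], 1L, sd)
    else singletons <- c(singletons, cts[j])
  }
  if (length(singletons) > 0L || any(s[!is.na(s)] == 0)) {
    computable <- s[!is.na(s) & s > 0]
    pooled <- if (length(computable) > 0L) median(computable)
              else if (modality == "expression") 0.1 else 0.05
    s[is.na(s) | s == 0] <- pooled
    if (length(singletons) > 0L)
      warning("single replicate for cell type(s) ",
              paste(singletons, collapse = ", "),
              "; pooled default scale ", format(pooled, digits = 4), " used")
  }
  out <- list(mean = m, sd = s, marker_type = rep(NA_integer_, p),
              modality = modality, p = p, k = length(cts),
              feature_ids = rownames(m), celltypes = cts)
  class(out) <- "panel_params"
  out
}

## Dirichlet draws: K x N matrix of simplex columns.
rdirichlet_cols <- function(n, alpha) {
  g <- matrix(rgamma(length(alpha) * n, shape = alpha), length(alpha), n)
  sweep(g, 2L, colSums(g), "/")
}

## Default measurement-noise level: the median within-cell-type linear-scale
## panel standard deviation implied by the parameters (expression), or 10% of
## the median beta-scale standard deviation (methylation).
default_noise_sd <- function(params) {
  if (params$modality == "expression") {
    lin_sd <- sqrt(exp(params$sd^2) - 1) * exp(params$mean + params$sd^2 / 2)
    median(lin_sd)
  } else {
    0.1 * median(params$sd)
  }
}

simulate_mixture_dataset <- function(params, n, alpha, noise_sd, seed,
                                     store_panels) {
  k <- params$k; p <- params$p
  if (length(alpha) != k)
    stop("alpha must have length k = ", k)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  h <- rdirichlet_cols(n, alpha)
  dimnames(h) <- list(params$celltypes, paste0("s", seq_len(n)))
  meth <- params$modality == "methylation"
  mixture <- matrix(0, p, n, dimnames = list(params$feature_ids, colnames(h)))
  panels <- if (store_panels)
    array(0, dim = c(p, k, n),
          dimnames = list(params$feature_ids, params$celltypes, colnames(h)))
  for (s in seq_len(n)) {
    panel <- matrix(rnorm(p * k, mean = params$mean, sd = params$sd), p, k)
    panel <- if (meth) pmin(pmax(panel, 0), 1) else exp(panel)
    if (store_panels) panels[, , s] <- panel
    col <- panel %*% h[, s]
    if (noise_sd > 0) col <- col + rnorm(p, 0, noise_sd)
    mixture[, s] <- if (meth) pmin(pmax(col, 0), 1) else pmax(col, 0)
  }
  attr(mixture, "modality") <- params$modality
  truth <- params$feature_ids[!is.na(params$marker_type)]
  out <- list(mixture = mixture, h_true = h,
              subject_panels = if (store_panels) panels,
              truth_markers = truth, alpha = alpha, noise_sd = noise_sd,
              seed = seed, params = params)
  class(out) <- "sim_dataset"
  out
}

#' Simulate a bulk expression mixture with ground truth
#'
#' Per subject, draws a pure panel (log-normal per feature per cell type from
#' the panel parameters), mixes the panel columns on the linear scale by
#' Dirichlet-distributed proportions, and adds Gaussian measurement noise
#' (clipped at zero).  The default Dirichlet parameters give realistic,
#' strongly unbalanced immune-cell proportions (mean fractions about 0.149,
#' 0.722, 0.076, 0.053 for four cell types).
#'
#' @param params A `"panel_params"` object ([default_panel_params()] or
#'   [estimate_panel_params()]).
#' @param n Number of samples.
#' @param alpha Dirichlet concentration parameters (length K); default
#'   `c(0.968, 4.706, 0.496, 0.347)` for the four-cell-type setting.
#' @param noise_sd Measurement-noise standard deviation (additive Gaussian on
#'   the measurement scale); the default is the median within-cell-type
#'   linear-scale panel standard deviation, a visible but not dominant
#'   array-level error.
#' @param seed Integer seed; the dataset is bit-reproducible given the seed.
#' @param store_panels Keep the per-subject pure panels (default `TRUE`).
#' @return An object of class `"sim_dataset"`: list with `mixture` (P x N),
#'   `h_true` (K x N), `subject_panels` (P x K x N array or `NULL`),
#'   `truth_markers` (planted marker feature IDs), `alpha`, `noise_sd`,
#'   `seed`, `params`.
#' @export
simulate_expression_dataset <- function(params, n,
                                        alpha = c(0.968, 4.706, 0.496, 0.347),
                                        noise_sd = NULL, seed = 1L,
                                        store_panels = TRUE) {
  stopifnot(inherits(params, "panel_params"))
  if (params$modality != "expression")
    stop("params are not expression-scale")
  if (is.null(noise_sd)) noise_sd <- default_noise_sd(params)
  simulate_mixture_dataset(params, n, alpha, noise_sd, seed, store_panels)
}

#' Simulate a DNA methylation mixture with ground truth
#'
#' As [simulate_expression_dataset()], but panels are Normal beta values
#' clipped to \[0, 1\] and the mixture is clipped to \[0, 1\] after noise.
#' The default six-cell-type Dirichlet parameters are
#' `c(0.89, 4.12, 0.47, 0.33, 0.61, 1.02)`; for four cell types the
#' expression default is used.
#'
#' @inheritParams simulate_expression_dataset
#' @param alpha Dirichlet parameters; if `NULL`, chosen by K (4 or 6).
#' @export
simulate_methylation_dataset <- function(params, n, alpha = NULL,
                                         noise_sd = NULL, seed = 1L,
                                         store_panels = TRUE) {
  stopifnot(inherits(params, "panel_params"))
  if (params$modality != "methylation")
    stop("params are not methylation-scale")
  if (is.null(alpha)) {
    alpha <- switch(as.character(params$k),
                    "4" = c(0.968, 4.706, 0.496, 0.347),
                    "6" = c(0.89, 4.12, 0.47, 0.33, 0.61, 1.02),
                    stop("no default alpha for k = ", params$k,
                         "; supply alpha explicitly"))
  }
  if (is.null(noise_sd)) noise_sd <- default_noise_sd(params)
  simulate_mixture_dataset(params, n, alpha, noise_sd, seed, store_panels)
}

#' Simulate mixed RNA-seq counts with planted cell-type-specific DE genes
#'
#' Generates negative-binomial counts for mixtures of K cell types.  Baseline
#' log2 expected counts are drawn from a broad Normal distribution; each of
#' `n_true_degs` genes is assigned one cell type and a log2 fold change drawn
#' from Normal(0, `lfc_sd`) truncated away from zero (|lfc| >= 0.5).
#' Expected counts are mixed across cell types by Dirichlet proportions,
#' scaled by a per-sample library-size factor, and counts are drawn from a
#' negative binomial with the given dispersion (`size = 1/dispersion`).
#'
#' @param p Number of genes.
#' @param n Number of samples.
#' @param k Number of cell types.
#' @param n_true_degs Number of planted cell-type-specific DE genes.
#' @param lfc_sd Standard deviation of the planted log2 fold changes
#'   (default 1.5).
#' @param dispersion Negative-binomial dispersion (default 0.1; must be > 0).
#' @param alpha Dirichlet parameters; defaults to the four-cell-type vector
#'   when `k = 4`, otherwise symmetric `rep(1, k)`.
#' @param libsize_range Range of the uniform per-sample library-size factors
#'   (default `c(0.7, 1.3)`).
#' @param seed Integer seed.
#' @return An object of class `"sim_counts"`: list with `counts` (integer
#'   P x N), `h_true` (K x N), `deg_truth` (data.frame: `feature`, `is_deg`,
#'   `celltype`, `lfc`), `alpha`, `dispersion`, `seed`.
#' @export
simulate_rnaseq_counts <- function(p, n, k, n_true_degs, lfc_sd = 1.5,
                                   dispersion = 0.1, alpha = NULL,
                                   libsize_range = c(0.7, 1.3), seed = 1L) {
  if (dispersion <= 0) stop("dispersion must be positive")
  if (n_true_degs > p) stop("n_true_degs exceeds the number of genes")
  if (is.null(alpha)) alpha <- if (k == 4L) c(0.968, 4.706, 0.496, 0.347)
                               else rep(1, k)
  if (length(alpha) != k) stop("alpha must have length k")
  set.seed(seed)
  ids <- paste0("g", seq_len(p))
  cts <- paste0("C", seq_len(k))
  base <- rnorm(p, mean = 5, sd = 2)          # log2 expected counts
  lfc <- rep(0, p)
  deg_type <- rep(NA_integer_, p)
  if (n_true_degs > 0L) {
    degs <- sample.int(p, n_true_degs)
    deg_type[degs] <- sample.int(k, n_true_degs, replace = TRUE)
    l <- rnorm(n_true_degs, 0, lfc_sd)
    while (any(abs(l) < 0.5))
      l[abs(l) < 0.5] <- rnorm(sum(abs(l) < 0.5), 0, lfc_sd)
    lfc[degs] <- l
  }
  mu_type <- matrix(2^base, p, k)             # linear expected counts per type
  for (k0 in seq_len(k)) {
    idx <- which(deg_type == k0)
    mu_type[idx, k0] <- 2^(base[idx] + lfc[idx])
  }
  h <- rdirichlet_cols(n, alpha)
  dimnames(h) <- list(cts, paste0("s", seq_len(n)))
  lib <- runif(n, libsize_range[1L], libsize_range[2L])
  mu <- (mu_type %*% h) * rep(lib, each = p)
  counts <- matrix(rnbinom(p * n, mu = mu, size = 1 / dispersion), p, n,
                   dimnames = list(ids, colnames(h)))
  out <- list(counts = counts, h_true = h,
              deg_truth = data.frame(feature = ids, is_deg = !is.na(deg_type),
                                     celltype = ifelse(is.na(deg_type), NA,
                                                       cts[deg_type]),
                                     lfc = lfc, stringsAsFactors = FALSE),
              alpha = alpha, dispersion = dispersion, lfc_sd = lfc_sd,
              seed = seed)
  class(out) <- "sim_counts"
  out
}

#' Library-size normalize counts onto the log2 scale
#'
#' Divides each sample by its library-size factor (column sum over the median
#' column sum) and returns `log2(normalized count + 1)`, the scale on which
#' the proportion-design linear model is applied to RNA-seq data.
#'
#' @param counts Integer count matrix (genes x samples).
#' @return Numeric matrix of the same shape.
#' @export
log2_normalize <- function(counts) {
  counts <- as.matrix(counts)
  f <- colSums(counts) / median(colSums(counts))
  if (any(f == 0)) stop("sample with zero total count")
  log2(sweep(counts, 2L, f, "/") + 1)
}
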