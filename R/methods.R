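#' @export
print.decomix <- function(x, ...) {
  cat("Reference-free deconvolution with iterative marker selection\n")
  cat("  cell types:", x$k, "  samples:", ncol(x$proportions),
      "  markers per iteration:", x$n_markers, "\n")
  cat("  chosen iteration:", x$chosen_iteration, "of",
      max(x$trace$iteration), " (reconstruction RMSE",
      format(x$rmse, digits = 6), ")\n")
  cat("  mean estimated proportions:",
      paste(sprintf("%s=%.3f", rownames(x$proportions),
                    rowMeans(x$proportions)), collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.decomix <- function(object, ...) {
  out <- list(trace = object$trace, chosen = object$chosen_iteration,
              prop_summary = t(apply(object$proportions, 1L, function(r)
                c(mean = mean(r), sd = sd(r), min = min(r), max = max(r)))),
              k = object$k, n = ncol(object$proportions))
  class(out) <- "summary.decomix"
  out
}

#' @export
print.summary.decomix <- function(x, ...) {
  cat("Iteration trace (chosen =", x$chosen, "):\n")
  print(x$trace, row.names = FALSE)
  cat("\nEstimated proportions across", x$n, "samples:\n")
  print(round(x$prop_summary, 4))
  invisible(x)
}

#' @export
coef.decomix <- function(object, ...) object$proportions

#' @export
fitted.decomix <- function(object, ...) object$signature %*% object$proportions

#' @export
residuals.decomix <- function(object, ...) object$y_chosen - fitted(object)

#' Predict proportions for new samples
#'
#' Applies the fitted signature matrix to new mixture samples via
#' reference-based constrained least squares ([reference_based_estimate()]).
#' Note the fitted components carry synthetic labels `C1..CK`.
#'
#' @param object A `"decomix"` fit.
#' @param newdata Mixture matrix (features x samples) containing the fitted
#'   marker features.
#' @param ... Unused.
#' @return A K x new-samples proportion matrix.
#' @export
predict.decomix <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$proportions)
  reference_based_estimate(as.matrix(newdata), object$signature)
}

#' Plot the iteration trace or estimated proportions
#'
#' @param x A `"decomix"` fit.
#' @param which `"trace"` draws the reconstruction RMSE per iteration with the
#'   chosen iteration highlighted; `"proportions"` draws per-cell-type
#'   boxplots of the estimated proportions.
#' @param ... Passed to the underlying plotting function.
#' @export
plot.decomix <- function(x, which = c("trace", "proportions"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    plot(x$trace$iteration, x$trace$rmse, type = "b", pch = 16,
         xlab = "iteration", ylab = "reconstruction RMSE", ...)
    points(x$chosen_iteration, x$rmse, col = "red", pch = 16, cex = 1.5)
    legend("topright", legend = "chosen (min RMSE)", col = "red",
           pch = 16, bty = "n")
  } else {
    boxplot(t(x$proportions), xlab = "component", ylab = "proportion", ...)
  }
  invisible(x)
}

#' Simulate new mixtures from a fitted factorization
#'
#' Draws synthetic mixture matrices `W H + E` where `E` is Gaussian noise
#' with the standard deviation of the model residuals, clipped to the valid
#' range of the modality.
#'
#' @param object A `"decomix"` fit.
#' @param nsim Number of simulated matrices.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` matrices of the same shape as the fitted subset.
#' @export
simulate.decomix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  s <- sd(residuals(object))
  lapply(seq_len(nsim), function(i) {
    out <- mu + rnorm(length(mu), sd = s)
    if (object$modality == "methylation") out <- pmin(pmax(out, 0), 1)
    else out <- pmax(out, 0)
    out
  })
}
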