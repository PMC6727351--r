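## Matrix input/output.  The canonical on-disk format is TSV with feature IDs
## in the first column (header "id") and sample IDs in the header row; CSV is
## accepted on read (chosen by file extension).  Values are written with 17
## significant digits so that write -> read round-trips doubles exactly.

#' Read a mixture (or signature/proportion) matrix from TSV/CSV
#'
#' Reads a features x samples matrix with feature identifiers in the first
#' column and sample identifiers in the header.  The delimiter is chosen from
#' the file extension (`.csv` uses comma, anything else tab).  The loader
#' validates the matrix: missing or non-numeric cells, duplicated feature or
#' sample identifiers, and (for methylation) beta values outside \[0, 1\] are
#' rejected with an error naming the offending entry.
#'
#' @param path Path to a TSV or CSV file.
#' @param modality `"expression"` (non-negative linear-scale intensities) or
#'   `"methylation"` (beta values in \[0, 1\]).
#' @return A numeric matrix with feature IDs as rownames, sample IDs as
#'   colnames, and a `"modality"` attribute.
#' @seealso [write_mixture()]
#' @export
read_mixture <- function(path, modality = c("expression", "methylation")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", comment.char = "",
                   quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) < 1L)
    stop("matrix file must have at least one feature row and one sample column")
  feat <- df[[1L]]
  samp <- colnames(df)[-1L]
  if (anyDuplicated(feat))
    stop("duplicated feature IDs: ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  if (anyDuplicated(samp))
    stop("duplicated sample IDs: ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(vals <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("missing or non-numeric value at feature '", feat[bad[1L, 1L]],
         "', sample '", samp[bad[1L, 2L]], "'")
  dimnames(vals) <- list(feat, samp)
  validate_mixture(vals, modality)
}

#' Write a matrix as TSV
#'
#' Writes a numeric matrix (mixture, signature, or proportion matrix) as
#' tab-separated text with row identifiers in an `id` column.  Values are
#' formatted with 17 significant digits, which round-trips IEEE doubles
#' exactly through [read_mixture()].
#'
#' @param x Numeric matrix with rownames and colnames.
#' @param path Output path; the parent directory must exist.
#' @export
write_mixture <- function(x, path) {
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("refusing to write an empty matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must have rownames and colnames")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  chr <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  out <- cbind(rownames(x), chr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(x)), collapse = "\t"), con)
  writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

## Shared validation for in-memory mixture matrices.
validate_mixture <- function(x, modality = c("expression", "methylation"),
                             tol = 1e-9) {
  modality <- match.arg(modality)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("mixture matrix must be numeric")
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop("missing value at feature '", rownames(x)[bad[1L]],
         "', sample '", colnames(x)[bad[2L]], "'")
  }
  if (modality == "methylation") {
    out <- which(x < -tol | x > 1 + tol, arr.ind = TRUE)
    if (nrow(out) > 0L)
      stop("methylation value ", x[out[1L, 1L], out[1L, 2L]],
           " outside [0, 1] at feature '", rownames(x)[out[1L, 1L]],
           "', sample '", colnames(x)[out[1L, 2L]], "'")
    x[] <- pmin(pmax(x, 0), 1)      # absorb sub-tolerance rounding
  }
  attr(x, "modality") <- modality
  x
}
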