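#' Construct a miRNA expression matrix
#'
#' A thin container for a features x samples intensity matrix: a numeric
#' matrix with feature IDs as rownames, sample IDs as colnames, and a
#' `space` attribute recording whether values are raw intensities or
#' median-normalized log2 intensities.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids character vector of unique miRNA identifiers
#'   (defaults to existing rownames).
#' @param sample_ids character vector of unique subject identifiers
#'   (defaults to existing colnames).
#' @param space one of `"raw"` or `"log2_normalized"`.
#' @return an `expr_matrix`: a numeric matrix with dimnames and a `space`
#'   attribute.
#' @examples
#' m <- expression_matrix(matrix(2^seq(1, 6), nrow = 3),
#'                        feature_ids = paste0("miR-", 1:3),
#'                        sample_ids = c("s1", "s2"))
#' expr_space(m)
#' @export
expression_matrix <- function(values,
                              feature_ids = rownames(values),
                              sample_ids = colnames(values),
                              space = c("raw", "log2_normalized")) {
  space <- match.arg(space)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("feature_%04d", seq_len(nrow(values)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("subject_%02d", seq_len(ncol(values)))
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    stop("feature_ids length (", length(feature_ids),
         ") does not match row count (", nrow(values), ")")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length (", length(sample_ids),
         ") does not match column count (", ncol(values), ")")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  attr(values, "space") <- space
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @describeIn expression_matrix Retrieve the space flag of an expression
#'   matrix (`"raw"` or `"log2_normalized"`).
#' @param m an `expr_matrix`.
#' @export
expr_space <- function(m) {
  sp <- attr(m, "space")
  if (is.null(sp)) "raw" else sp
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("miRNA expression matrix: %d features x %d samples [%s]\n",
              nrow(x), ncol(x), expr_space(x)))
  n <- min(5L, nrow(x))
  k <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(k), drop = FALSE])
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more features)\n", sep = "")
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "space") <- attr(x, "space")
    class(out) <- c("expr_matrix", "matrix", "array")
  }
  out
}

#' Median-normalize and log2-transform raw intensities
#'
#' Each sample column is rescaled multiplicatively so that its median equals
#' the global target (the median of the per-sample medians), then values are
#' log2 transformed.  This is the standard microarray intensity convention:
#' scaling keeps values positive so the log is defined, and after the
#' transform every sample shares the same median log2 intensity.
#'
#' Rescaling an input column by c > 0 leaves the output unchanged as long
#' as the target (the middle order statistic of the per-sample medians) is
#' unaffected; when the rescaled column's median is itself the target, all
#' log2 values shift by a common constant instead.  With an odd number of
#' features the per-sample log2 medians equalize exactly (the median is an
#' order statistic and commutes with log2); with an even count the
#' equalization is exact on the intensity scale and approximate after the
#' transform.
#'
#' @param m an `expr_matrix` in `raw` space with strictly positive values.
#' @return an `expr_matrix` in `log2_normalized` space.
#' @export
median_normalize_log2 <- function(m) {
  if (expr_space(m) != "raw") {
    stop("median_normalize_log2 expects a matrix in raw space")
  }
  bad <- which(unclass(m) <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("nonpositive raw intensity at feature '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  med <- apply(unclass(m), 2, stats::median)
  target <- stats::median(med)
  scaled <- sweep(unclass(m), 2, target / med, `*`)
  expression_matrix(log2(scaled),
                    feature_ids = rownames(m), sample_ids = colnames(m),
                    space = "log2_normalized")
}

#' Keep features expressed in every sample
#'
#' Retains exactly the features whose (log2-normalized) value is strictly
#' greater than 0 in all samples; on the raw intensity scale this means
#' intensity > 1 everywhere.  Feature order is preserved.
#'
#' @param m an `expr_matrix` in `log2_normalized` space (set
#'   `require_log2 = FALSE` to apply the same rule on raw values).
#' @param require_log2 enforce the log2 space flag (default `TRUE`).
#' @return the filtered `expr_matrix`; dropped features are reported via
#'   `message()`.
#' @export
filter_expressed <- function(m, require_log2 = TRUE) {
  if (require_log2 && expr_space(m) != "log2_normalized") {
    stop("filter_expressed expects a log2_normalized matrix; ",
         "run median_normalize_log2 first or set require_log2 = FALSE")
  }
  keep <- apply(unclass(m) > 0, 1, all)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("filter_expressed: dropped %d of %d features not > 0 in every sample",
                    dropped, nrow(m)))
  }
  if (!any(keep)) {
    warning("filter_expressed: no feature passed the > 0 filter")
  }
  m[keep, , drop = FALSE]
}

#' Standardize each feature row to mean 0, SD 1
#'
#' Row-wise z-scoring with the sample (n-1) standard deviation, as used for
#' heatmap displays of the candidate panel.
#'
#' @param m an `expr_matrix` or plain numeric matrix.
#' @return a plain numeric matrix with zero-mean, unit-SD rows.
#' @export
standardize_rows <- function(m) {
  v <- unclass(m)
  attr(v, "space") <- NULL
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  zero <- which(sdv == 0 | !is.finite(sdv))
  if (length(zero) > 0) {
    stop("zero-variance feature row(s): ",
         paste(rownames(v)[zero[seq_len(min(5, length(zero)))]], collapse = ", "))
  }
  (v - mu) / sdv
}
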