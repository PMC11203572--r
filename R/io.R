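#' Read an expression matrix from TSV or GEO series-matrix text
#'
#' The TSV dialect is the one written by [write_cohort()]: tab-separated,
#' first row the sample IDs, first column the miRNA IDs.  The
#' series-matrix dialect skips "!"-prefixed metadata lines and reads the
#' table between the `!series_matrix_table_begin` / `!series_matrix_table_end`
#' markers.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"series_matrix"`.
#' @param space the space flag to attach (`"raw"` or `"log2_normalized"`).
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, dialect = c("tsv", "series_matrix"),
                            space = c("log2_normalized", "raw")) {
  dialect <- match.arg(dialect)
  space <- match.arg(space)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "series_matrix") {
    lines <- readLines(path)
    b <- grep("^!series_matrix_table_begin", lines)
    e <- grep("^!series_matrix_table_end", lines)
    if (length(b) != 1 || length(e) != 1 || e <= b + 1) {
      stop("malformed series-matrix file: table markers not found")
    }
    txt <- lines[(b + 1):(e - 1)]
    txt <- txt[!startsWith(txt, "!")]
    df <- utils::read.delim(text = paste(txt, collapse = "\n"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2) stop("malformed header: expected ID column + samples")
  ids <- as.character(df[[1]])
  # series matrices quote IDs
  ids <- gsub('^"|"$', "", ids)
  if (anyDuplicated(ids)) {
    stop("duplicate feature ID(s): ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
               collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    for (j in seq_along(df)[-1]) {
      num <- suppressWarnings(as.numeric(df[[j]]))
      if (anyNA(num) && !anyNA(df[[j]])) {
        stop(sprintf("non-numeric cell at row %d, column '%s'",
                     which(is.na(num))[1], names(df)[j]))
      }
    }
    stop("non-numeric values in expression table")
  }
  expression_matrix(vals, feature_ids = ids, sample_ids = colnames(df)[-1],
                    space = space)
}

#' Write an expression matrix as TSV
#' @param expr an `expr_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(mirna_id = rownames(expr), unclass(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt_dates <- function(x) {
  vapply(x, function(d) paste(format(as.Date(d), "%Y-%m-%d"), collapse = ";"),
         character(1))
}

parse_dates <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) as.Date(character(0)) else
      as.Date(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Write / read the clinical table as CSV
#'
#' Columns: `subject_id, sex, age, disease_duration, edss_t0..edss_t4,
#' pira, raw, relapse_onsets, cdw_events`; date lists are ISO-8601,
#' semicolon-separated.
#'
#' @param cohort a `mir_cohort` data.frame.
#' @param path file path.
#' @return `write_clinical` returns `path` invisibly; `read_clinical`
#'   returns a `mir_cohort`.
#' @export
write_clinical <- function(cohort, path) {
  df <- as.data.frame(cohort[setdiff(names(cohort),
                                     c("relapse_onsets", "cdw_events"))])
  df$relapse_onsets <- fmt_dates(cohort$relapse_onsets)
  df$cdw_events <- fmt_dates(cohort$cdw_events)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  if (anyDuplicated(df$subject_id)) stop("duplicate subject IDs")
  if ("relapse_onsets" %in% names(df)) {
    df$relapse_onsets <- parse_dates(df$relapse_onsets)
  }
  if ("cdw_events" %in% names(df)) {
    df$cdw_events <- parse_dates(df$cdw_events)
  }
  class(df) <- c("mir_cohort", "data.frame")
  df
}

#' Write a synthetic cohort to disk
#'
#' Writes the expression matrix as TSV, the clinical table as CSV, and
#' the truth record (requested vs realized correlations) as YAML; the
#' files round-trip losslessly through [read_expression()] and
#' [read_clinical()].
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(out_dir, "expression.tsv"),
             clinical = file.path(out_dir, "clinical.csv"),
             truth = file.path(out_dir, "truth.yaml"))
  write_expression(cohort$expression, paths["expression"])
  write_clinical(cohort$clinical, paths["clinical"])
  tr <- cohort$truth
  yaml::write_yaml(list(
    n_informative = nrow(tr),
    correlation_mode = cohort$config$correlation_mode,
    features = if (nrow(tr)) lapply(seq_len(nrow(tr)), function(i)
      as.list(tr[i, , drop = FALSE])) else list()
  ), paths["truth"], precision = 15)
  invisible(paths)
}
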