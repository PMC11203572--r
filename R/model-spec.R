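#' Specify a logistic or linear model over miRNA predictors
#'
#' A model specification is a family (logistic for PIRA, linear for EDSS
#' change), a predictor set, and a term set over those predictors: main
#' effects (`"feature"`) and pairwise interactions (`"feature1:feature2"`,
#' canonically ordered alphabetically), plus an always-present intercept.
#' Marginality is deliberately not enforced: an interaction term may
#' appear without the main effects of the features it involves, since the
#' significance-constrained search explores that full space.
#'
#' @param predictors character vector of feature IDs.
#' @param terms character vector of term labels; defaults to all main
#'   effects of `predictors`.
#' @param family `"logistic"` or `"linear"`.
#' @param response `"pira"` (logistic) or `"edss_change"` (linear).
#' @return list of class `model_spec`.
#' @examples
#' model_spec(c("a", "b"), c("a", "a:b"), family = "logistic")
#' @export
model_spec <- function(predictors, terms = predictors,
                       family = c("logistic", "linear"),
                       response = NULL) {
  family <- match.arg(family)
  if (is.null(response)) {
    response <- if (family == "logistic") "pira" else "edss_change"
  }
  predictors <- as.character(predictors)
  if (anyDuplicated(predictors)) stop("duplicate predictors")
  terms <- vapply(as.character(terms), canonical_term, character(1))
  if (length(terms) == 0) stop("at least one non-intercept term required")
  if (anyDuplicated(terms)) stop("duplicate terms")
  for (tm in terms) {
    f <- term_features(tm)
    if (length(f) == 2 && f[1] == f[2]) {
      stop("interaction term must reference distinct features: ", tm)
    }
    if (!all(f %in% predictors)) {
      stop("term '", tm, "' references features outside the predictor set")
    }
  }
  structure(list(family = family, response = response,
                 predictors = predictors, terms = unname(terms)),
            class = "model_spec")
}

canonical_term <- function(term) {
  f <- strsplit(term, ":", fixed = TRUE)[[1]]
  if (length(f) > 2) stop("only pairwise interactions are supported: ", term)
  paste(sort(f), collapse = ":")
}

term_features <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("%s model for %s: %d predictor(s), %d term(s) + intercept\n",
              x$family, x$response, length(x$predictors), length(x$terms)))
  cat("  terms: ", paste(x$terms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Build the design matrix (intercept first) for a spec from a
# features x samples expression matrix.  Interaction columns are
# elementwise products of the uncentered log2 expression vectors.
build_design <- function(spec, expr) {
  missing <- setdiff(spec$predictors, rownames(expr))
  if (length(missing)) {
    stop("features missing from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  v <- unclass(expr)
  cols <- vapply(spec$terms, function(tm) {
    f <- term_features(tm)
    if (length(f) == 1) v[f, ] else v[f[1], ] * v[f[2], ]
  }, numeric(ncol(v)))
  if (!is.matrix(cols)) cols <- matrix(cols, nrow = 1)  # single-sample input
  X <- cbind(`(Intercept)` = 1, cols)
  colnames(X) <- c("(Intercept)", spec$terms)
  X
}

# All terms over a predictor subset, mains first, then pairwise
# interactions in combn order; this ordering defines the enumeration
# bitmask layout.
all_terms <- function(predictors) {
  ints <- if (length(predictors) >= 2) {
    apply(utils::combn(predictors, 2), 2,
          function(p) paste(sort(p), collapse = ":"))
  } else character(0)
  c(predictors, ints)
}

#' Enumerate candidate model specifications
#'
#' For every `k`-subset of `candidates`, yields every nonempty subset of
#' the `k` main-effect terms plus the `choose(k, 2)` pairwise interaction
#' terms — `2^(k + choose(k, 2)) - 1` term sets per predictor subset, in
#' deterministic lexicographic order (subsets by [utils::combn()], term
#' sets by binary counting with mains in the low bits).
#'
#' This materializes the full list; for k = 4 over 9 candidates that is
#' 128,898 specifications, so prefer [search_best()] (which streams the
#' same space through compiled code) for actual searches.
#'
#' @param candidates character vector of candidate feature IDs.
#' @param k predictor-subset size.
#' @param family,response as in [model_spec()].
#' @return list of `model_spec` objects.
#' @examples
#' length(enumerate_models(c("a", "b"), k = 2))  # 2^3 - 1 = 7
#' @export
enumerate_models <- function(candidates, k, family = "logistic",
                             response = NULL) {
  candidates <- as.character(candidates)
  if (k <= 0) stop("k must be positive")
  if (k > length(candidates)) stop("k exceeds the number of candidates")
  subsets <- utils::combn(candidates, k, simplify = FALSE)
  out <- vector("list", 0)
  for (sub in subsets) {
    terms <- all_terms(sub)
    nt <- length(terms)
    for (mask in seq_len(2^nt - 1)) {
      sel <- terms[bitwAnd(mask, bitwShiftL(1L, seq_len(nt) - 1L)) != 0L]
      out[[length(out) + 1L]] <- model_spec(sub, sel, family = family,
                                            response = response)
    }
  }
  out
}

#' @describeIn enumerate_models Number of term sets per k-predictor
#'   subset: `2^(k + choose(k, 2)) - 1`.
#' @export
count_term_sets <- function(k) 2^(k + choose(k, 2)) - 1
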