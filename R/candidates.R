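#' Pearson correlation with two-sided t-test
#'
#' Sample Pearson correlation with the two-sided p-value from the t
#' distribution on n - 2 degrees of freedom
#' (`t = r * sqrt((n - 2) / (1 - r^2))`).  When `y` is a 0/1 indicator
#' (e.g. PIRA status) this is the point-biserial correlation, computed as
#' ordinary Pearson on the binary coding.
#'
#' @param x,y numeric vectors of equal length n >= 3, neither constant.
#' @return list with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Shapiro-Wilk normality p-value
#'
#' Royston's Shapiro-Wilk test as implemented in [stats::shapiro.test()];
#' a p-value above the chosen level indicates consistency with a normal
#' distribution.
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @return the p-value.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  stats::shapiro.test(x)$p.value
}

#' Screen miRNAs correlated with both PIRA and EDSS change
#'
#' For every feature, computes the Pearson correlation (with two-sided
#' p-value) of its expression against PIRA status (0/1) and against the
#' 24-month EDSS change (T4 - T0), plus a Shapiro-Wilk normality p-value
#' of the expression vector.  A feature passes when both correlations are
#' significant at `alpha` (no multiple-testing correction, per the
#' screening design; set `adjust = "BH"` for a Benjamini-Hochberg
#' sensitivity variant) and, in strict mode, when its expression is
#' consistent with normality.
#'
#' Subjects missing the 24-month EDSS are excluded listwise with a
#' warning.
#'
#' @param expr an `expr_matrix` (log2-normalized, filtered), columns
#'   matching `cohort` subjects.
#' @param cohort a `mir_cohort` with `pira`, `edss_t0`, `edss_t4`.
#' @param alpha per-feature significance level (default 0.05).
#' @param strict_normality additionally require `shapiro_p > alpha_norm`.
#' @param alpha_norm normality level for strict mode.
#' @param adjust p-value adjustment across features: `"none"` (default)
#'   or any method of [stats::p.adjust()].
#' @return data.frame of class `mir_candidates`, one row per feature
#'   (columns `mirna_id`, `r_pira`, `p_pira`, `r_edss`, `p_edss`,
#'   `shapiro_p`, `passed`), sorted by `mirna_id` with passing features
#'   first.
#' @export
select_candidates <- function(expr, cohort, alpha = 0.05,
                              strict_normality = FALSE, alpha_norm = 0.05,
                              adjust = "none") {
  stopifnot(is.data.frame(cohort),
            all(c("pira", "edss_t0", "edss_t4") %in% names(cohort)))
  if (ncol(expr) != nrow(cohort)) {
    stop("expression has ", ncol(expr), " samples but cohort has ",
         nrow(cohort), " subjects")
  }
  keep <- !is.na(cohort$edss_t4) & !is.na(cohort$edss_t0)
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) missing EDSS T0/T4 excluded listwise")
  }
  pira <- cohort$pira[keep]
  dedss <- cohort$edss_t4[keep] - cohort$edss_t0[keep]
  v <- unclass(expr)[, keep, drop = FALSE]

  nfeat <- nrow(v)
  r_pira <- p_pira <- r_edss <- p_edss <- sw <- rep(NA_real_, nfeat)
  for (i in seq_len(nfeat)) {
    if (stats::sd(v[i, ]) == 0) next   # constant feature: leave NA, never passes
    cp <- pearson_r(v[i, ], pira)
    ce <- pearson_r(v[i, ], dedss)
    r_pira[i] <- cp$r; p_pira[i] <- cp$p
    r_edss[i] <- ce$r; p_edss[i] <- ce$p
    sw[i] <- shapiro_wilk(v[i, ])
  }
  if (adjust != "none") {
    p_pira <- stats::p.adjust(p_pira, method = adjust)
    p_edss <- stats::p.adjust(p_edss, method = adjust)
  }
  passed <- !is.na(p_pira) & !is.na(p_edss) &
    p_pira < alpha & p_edss < alpha
  if (strict_normality) passed <- passed & !is.na(sw) & sw > alpha_norm

  out <- data.frame(mirna_id = rownames(v), r_pira = r_pira, p_pira = p_pira,
                    r_edss = r_edss, p_edss = p_edss, shapiro_p = sw,
                    passed = passed, stringsAsFactors = FALSE)
  out <- out[order(!out$passed, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "edss_change_shapiro_p") <- if (stats::sd(dedss) > 0)
    shapiro_wilk(dedss) else NA_real_
  class(out) <- c("mir_candidates", "data.frame")
  out
}

#' @export
print.mir_candidates <- function(x, ...) {
  if (is.null(x$passed)) return(print.data.frame(x, ...))  # column subset
  cat(sprintf("miRNA candidate screen: %d features, %d passed (alpha = %g)\n",
              nrow(x), sum(x$passed), attr(x, "alpha")))
  print.data.frame(utils::head(x[x$passed, , drop = FALSE], 15), digits = 3)
  invisible(x)
}
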