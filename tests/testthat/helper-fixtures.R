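# Shared fixtures, built in code at test time.

# Minimal clinical table: n subjects, given PIRA flags and EDSS T0/T4.
toy_cohort <- function(pira, edss_t0, edss_t4) {
  n <- length(pira)
  structure(data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    sex = rep("F", n), age = rep(40, n), disease_duration = rep(5, n),
    edss_t0 = edss_t0, edss_t1 = edss_t0, edss_t2 = edss_t0,
    edss_t3 = edss_t4, edss_t4 = edss_t4,
    pira = as.integer(pira), raw = 0L,
    stringsAsFactors = FALSE
  ), class = c("mir_cohort", "data.frame"))
}

# Expression matrix from a plain numeric matrix (log2 space).
toy_expr <- function(values, feature_ids = NULL, sample_ids = NULL) {
  expression_matrix(values,
                    feature_ids = feature_ids %||%
                      sprintf("f%02d", seq_len(nrow(values))),
                    sample_ids = sample_ids %||%
                      sprintf("s%02d", seq_len(ncol(values))),
                    space = "log2_normalized")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent textbook Pearson correlation + two-sided t-test p-value,
# written from the defining sums (the oracle for pearson_r and the
# generator's exact mode).
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Brute-force AUC by pair counting: (concordant + 0.5 * ties) / (np * nn).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  d <- outer(pos, neg, `-`)
  (sum(d > 0) + 0.5 * sum(d == 0)) / (length(pos) * length(neg))
}

# Small informative cohort used by search/resampling tests: moderate panel
# so screens and searches stay fast.
small_sim <- function(seed = 3, n_features = 60) {
  simulate_cohort(sim_config(n_features = n_features, seed = seed))
}
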