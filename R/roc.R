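#' ROC curve, AUC, and maximum-Youden threshold
#'
#' Thresholds are the unique observed scores in descending order with a
#' leading +Inf sentinel; a subject is predicted positive when
#' `score >= threshold`.  The AUC is the trapezoid area under (FPR, TPR),
#' which equals the Mann-Whitney concordance probability (ties counted
#' half).  The Youden threshold maximizes J = TPR - FPR; ties are broken
#' toward the smallest threshold.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (1 = positive class, PIRA).
#' @return object of class `mir_roc` with `thresholds`, `tpr`, `fpr`,
#'   `auc`, `youden_threshold`, `youden_j`.
#' @examples
#' r <- roc_auc(c(.9, .8, .4, .3), c(1, 1, 0, 0))
#' r$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0 || nn == 0) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nn,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  jmax <- max(j)
  # ties toward the smallest threshold; exclude the Inf sentinel unless alone
  cand <- which(j >= jmax - 1e-15)
  pick <- cand[which.min(thr[cand])]
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 youden_threshold = thr[pick], youden_j = j[pick],
                 n_pos = np, n_neg = nn),
            class = "mir_roc")
}

#' @export
print.mir_roc <- function(x, ...) {
  cat(sprintf("ROC: %d positives / %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  cat(sprintf("maximum Youden J = %.4f at threshold %.4g\n",
              x$youden_j, x$youden_threshold))
  invisible(x)
}

#' @export
plot.mir_roc <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "false positive rate", ylab = "true positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

# Shared resampling driver: repeatedly perturb (resample/permute/swap
# features), refit the spec, and record the apparent AUC.  Degenerate
# replicates (one-class outcome, failed fit) are redrawn up to
# `max_redraws` times, then counted as failures.
resample_auc <- function(expr, outcome, spec, n_reps, seed, perturb,
                         guard = 1e3, max_redraws = 100L) {
  y <- resolve_response(spec, outcome)
  set.seed(as.integer(seed))
  aucs <- rep(NA_real_, n_reps)
  failures <- 0L
  for (r in seq_len(n_reps)) {
    done <- FALSE
    for (try in seq_len(max_redraws)) {
      pd <- perturb(y, expr)
      yr <- pd$y
      if (length(unique(yr)) < 2) next
      X <- tryCatch(build_design(pd$spec, pd$expr), error = function(e) NULL)
      if (is.null(X)) next
      Xs <- X[pd$idx, , drop = FALSE]
      fam <- if (spec$family == "logistic") 0L else 1L
      f <- tryCatch(fit_single_cpp(Xs, yr, fam), error = function(e) NULL)
      if (is.null(f) || !f$ok) next
      score <- as.numeric(Xs %*% f$coef)
      if (spec$family == "logistic") score <- stats::plogis(score)
      a <- tryCatch(roc_auc(score, yr)$auc, error = function(e) NA_real_)
      if (is.na(a)) next
      aucs[r] <- a
      done <- TRUE
      break
    }
    if (!done) failures <- failures + 1L
  }
  list(aucs = aucs[!is.na(aucs)], failures = failures)
}

new_null_distribution <- function(kind, aucs, n_reps, observed = NA_real_,
                                  failures = 0L, seed = NA_integer_) {
  emp_p <- if (kind == "bootstrap") NA_real_ else
    (1 + sum(aucs >= observed)) / (1 + length(aucs))
  structure(list(kind = kind, n_reps = n_reps, auc_samples = aucs,
                 observed_auc = observed, empirical_p = emp_p,
                 mean = mean(aucs), sd = stats::sd(aucs),
                 failures = failures, seed = seed),
            class = "mir_null")
}

#' @export
print.mir_null <- function(x, ...) {
  cat(sprintf("%s AUC distribution: %d replicates (%d failed)\n",
              x$kind, length(x$auc_samples), x$failures))
  cat(sprintf("  mean +/- SD = %.3f +/- %.3f\n", x$mean, x$sd))
  if (!is.na(x$empirical_p)) {
    cat(sprintf("  observed AUC = %.3f, empirical p = %.4g (add-one)\n",
                x$observed_auc, x$empirical_p))
  }
  invisible(x)
}

#' @export
plot.mir_null <- function(x, ...) {
  graphics::hist(x$auc_samples, breaks = 30, xlim = c(0, 1),
                 main = sprintf("%s AUC distribution", x$kind),
                 xlab = "AUC", ...)
  if (!is.na(x$observed_auc)) abline(v = x$observed_auc, col = "red", lwd = 2)
  invisible(x)
}

# Observed apparent AUC of a spec refit on the full data.
observed_auc <- function(expr, outcome, spec, guard = 1e3) {
  fit <- fit_glm(spec, expr, outcome, guard = guard)
  roc_auc(fit$fitted, resolve_response(spec, outcome))$auc
}

#' Bootstrap distribution of the apparent AUC
#'
#' For each replicate, subjects are resampled with replacement, the model
#' structure is refit on the resample, and the apparent AUC on the
#' resample is recorded.  Replicates where a class vanishes or the fit
#' fails are redrawn (up to 100 times, then counted as failures).
#' Reported as mean +/- SD; because the structure is refit on each
#' resample, the bootstrap mean typically exceeds the apparent AUC
#' (optimism of refitting).
#'
#' @param expr an `expr_matrix`.
#' @param outcome a `mir_cohort` or response vector.
#' @param spec the model structure (a [model_spec()]).
#' @param n_reps number of bootstrap replicates (reference analysis:
#'   1000).
#' @param seed RNG seed.
#' @return a `mir_null` of kind `"bootstrap"`.
#' @export
bootstrap_auc <- function(expr, outcome, spec, n_reps = 1000, seed = 1L) {
  n <- ncol(expr)
  perturb <- function(y, e) {
    idx <- sample.int(n, n, replace = TRUE)
    list(y = y[idx], expr = e, spec = spec, idx = idx)
  }
  rs <- resample_auc(expr, outcome, spec, n_reps, sub_seed(seed, 11), perturb)
  new_null_distribution("bootstrap", rs$aucs, n_reps,
                        observed = observed_auc(expr, outcome, spec),
                        failures = rs$failures, seed = as.integer(seed))
}

#' Label-permutation null distribution of the AUC
#'
#' Each replicate permutes the PIRA labels uniformly, refits the model
#' structure, and records the apparent AUC; the empirical p-value
#' compares the observed apparent AUC against this null with the add-one
#' correction `(1 + #\{null >= observed\}) / (1 + n_reps)`.
#'
#' @inheritParams bootstrap_auc
#' @param n_reps number of permutations (reference analysis: 1000).
#' @return a `mir_null` of kind `"label_permutation"`.
#' @export
permute_labels_null <- function(expr, outcome, spec, n_reps = 1000,
                                seed = 1L) {
  n <- ncol(expr)
  perturb <- function(y, e) {
    list(y = y[sample.int(n)], expr = e, spec = spec, idx = seq_len(n))
  }
  rs <- resample_auc(expr, outcome, spec, n_reps, sub_seed(seed, 12), perturb)
  new_null_distribution("label_permutation", rs$aucs, n_reps,
                        observed = observed_auc(expr, outcome, spec),
                        failures = rs$failures, seed = as.integer(seed))
}

#' Predictor-randomization null distribution of the AUC
#'
#' Each replicate draws as many distinct features as the model has
#' predictors, uniformly from `pool` excluding the model's own
#' predictors, substitutes them positionally into the same term
#' structure, refits, and records the apparent AUC.
#'
#' @inheritParams bootstrap_auc
#' @param pool candidate feature IDs to draw from (default: all features
#'   in `expr`); must exceed the predictor count after excluding the
#'   model's own predictors.
#' @param n_reps number of randomizations (reference analysis: 10,000).
#' @return a `mir_null` of kind `"predictor_randomization"`.
#' @export
randomize_predictors_null <- function(expr, outcome, spec,
                                      pool = rownames(expr),
                                      n_reps = 10000, seed = 1L) {
  pool <- setdiff(pool, spec$predictors)
  npred <- length(spec$predictors)
  if (length(pool) < npred) {
    stop("feature pool too small: ", length(pool),
         " non-optimal feature(s) for ", npred, " predictor slot(s)")
  }
  n <- ncol(expr)
  perturb <- function(y, e) {
    repl <- sample(pool, npred)
    map <- stats::setNames(repl, spec$predictors)
    new_terms <- vapply(spec$terms, function(tm) {
      paste(sort(unname(map[term_features(tm)])), collapse = ":")
    }, character(1))
    sp <- tryCatch(model_spec(repl, new_terms, family = spec$family,
                              response = spec$response),
                   error = function(e2) NULL)
    if (is.null(sp)) sp <- spec   # duplicate collapse; will be redrawn
    list(y = y, expr = e, spec = sp, idx = seq_len(n))
  }
  rs <- resample_auc(expr, outcome, spec, n_reps, sub_seed(seed, 13), perturb)
  new_null_distribution("predictor_randomization", rs$aucs, n_reps,
                        observed = observed_auc(expr, outcome, spec),
                        failures = rs$failures, seed = as.integer(seed))
}

#' Score a cohort with the frozen PIRA reference classifier
#'
#' Applies the frozen logistic reference model ([reference_model()]
#' `"eq1_pira"`) to every subject, classifies at its stored 0.277
#' threshold, and returns the ROC against the clinical PIRA labels plus
#' the per-subject scores and predicted classes.
#'
#' @param expr an `expr_matrix` containing the four reference predictors.
#' @param cohort a `mir_cohort` with `pira` labels.
#' @return list with `roc` (a `mir_roc`), `scores`, `classes`, and
#'   `threshold`.
#' @export
evaluate_reference_classifier <- function(expr, cohort) {
  m <- reference_model("eq1_pira")
  scores <- predict(m, expr, type = "response")
  pira <- if (is.data.frame(cohort)) cohort$pira else as.integer(cohort)
  list(roc = roc_auc(scores, pira),
       scores = scores,
       classes = as.integer(scores >= m$threshold),
       threshold = m$threshold)
}
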