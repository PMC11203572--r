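#' Assemble a pipeline configuration
#'
#' Numeric defaults mirror the reference analysis: per-feature
#' significance 0.05, four predictors out of the screened candidates, AIC
#' ranking, and 1000 bootstrap / 1000 label-permutation / 10,000
#' predictor-randomization replicates.
#'
#' @param expression path to an expression TSV (or `NULL` to simulate).
#' @param clinical path to a clinical CSV (or `NULL` to simulate).
#' @param out_dir output directory for the report bundle.
#' @param sim a [sim_config()] used when no input paths are given.
#' @param normalize apply [median_normalize_log2()] (set `FALSE` when the
#'   input is already log2-normalized).
#' @param alpha candidate-screen and Wald significance level.
#' @param k predictor count of the exhaustive search.
#' @param criterion information criterion for ranking.
#' @param n_boot,n_label_perm,n_pred_rand resampling replicate counts.
#' @param seed master seed for all resampling.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, clinical = NULL,
                            out_dir = tempfile("piramir_run_"),
                            sim = sim_config(),
                            normalize = FALSE,
                            alpha = 0.05, k = 4,
                            criterion = "AIC",
                            n_boot = 1000, n_label_perm = 1000,
                            n_pred_rand = 10000,
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, k >= 1,
            n_boot >= 1, n_label_perm >= 1, n_pred_rand >= 1)
  structure(list(expression = expression, clinical = clinical,
                 out_dir = out_dir, sim = sim, normalize = normalize,
                 alpha = alpha, k = as.integer(k), criterion = criterion,
                 n_boot = n_boot, n_label_perm = n_label_perm,
                 n_pred_rand = n_pred_rand, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Preprocessing (optional median normalization + expression filter) →
#' candidate screen (dual Pearson correlation vs PIRA and EDSS change) →
#' exhaustive significance-constrained logistic search for PIRA and
#' linear search for EDSS change → ROC/Youden evaluation and the three
#' robustness procedures for the logistic winner.  All tabular outputs
#' are tab-separated with 12-significant-digit floats; the best models
#' are serialized as YAML in the same schema as the frozen reference
#' constants.
#'
#' @param config a [pipeline_config()].
#' @return the report bundle (named list), invisibly; files are written
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  logf("pipeline start; effective configuration:")
  cfg_dump <- config
  cfg_dump$sim <- unclass(cfg_dump$sim)
  cfg_dump$sim$informative_spec <- NULL
  cat(yaml::as.yaml(lapply(unclass(cfg_dump), function(x)
    if (is.atomic(x) || is.list(x)) x else format(x))),
    file = log_path, append = TRUE)

  ## inputs
  if (!is.null(config$expression)) {
    expr <- read_expression(config$expression,
                            space = if (config$normalize) "raw"
                                    else "log2_normalized")
    cohort <- read_clinical(config$clinical)
    logf("loaded expression ", nrow(expr), " x ", ncol(expr),
         " and clinical table (", nrow(cohort), " subjects)")
  } else {
    sc <- simulate_cohort(config$sim)
    expr <- sc$expression
    cohort <- sc$clinical
    logf("simulated cohort: ", ncol(expr), " subjects, ", nrow(expr),
         " features, ", sum(cohort$pira), " PIRA+")
  }

  ## preprocess
  if (config$normalize) expr <- median_normalize_log2(expr)
  expr <- filter_expressed(expr)
  logf("after expression filter: ", nrow(expr), " features")

  ## trajectory report
  traj <- edss_trajectory_report(cohort)
  write_tsv_report(traj, file.path(config$out_dir, "edss_trajectory.tsv"))

  ## candidate screen
  cand <- select_candidates(expr, cohort, alpha = config$alpha)
  write_tsv_report(cand, file.path(config$out_dir, "candidates.tsv"))
  n_pass <- sum(cand$passed)
  logf("candidate screen: ", n_pass, " of ", nrow(cand),
       " features passed at alpha = ", config$alpha)
  if (n_pass < config$k) {
    stop("pipeline stage candidate_filter: only ", n_pass,
         " candidate(s) passed but k = ", config$k)
  }

  ## model searches
  search_log <- search_best(expr, cohort, cand, k = config$k,
                            family = "logistic",
                            criterion = config$criterion,
                            alpha = config$alpha)
  logf("logistic search: ", search_log$n_models, " models, ",
       search_log$n_allsig, " all-significant; best = ",
       paste(search_log$best$spec$predictors, collapse = ", "))
  search_lin <- search_best(expr, cohort, cand, k = config$k,
                            family = "linear",
                            criterion = config$criterion,
                            alpha = config$alpha)
  logf("linear search: best predictors = ",
       paste(search_lin$best$spec$predictors, collapse = ", "))
  write_tsv_report(search_log$table,
                   file.path(config$out_dir, "search_logistic.tsv"))
  write_tsv_report(search_lin$table,
                   file.path(config$out_dir, "search_linear.tsv"))

  ## classifier evaluation + robustness
  best <- search_log$best
  roc <- roc_auc(best$fitted, resolve_response(best$spec, cohort))
  best$threshold <- roc$youden_threshold
  write_model_yaml(best, file.path(config$out_dir, "best_logistic.yaml"))
  write_model_yaml(search_lin$best,
                   file.path(config$out_dir, "best_linear.yaml"))
  write_tsv_report(
    data.frame(threshold = roc$thresholds, fpr = roc$fpr, tpr = roc$tpr),
    file.path(config$out_dir, "roc.tsv"))
  logf("apparent AUC = ", sprintf("%.4f", roc$auc),
       ", Youden cutoff = ", sprintf("%.4f", roc$youden_threshold))

  boot <- bootstrap_auc(expr, cohort, best$spec, n_reps = config$n_boot,
                        seed = config$seed)
  perm <- permute_labels_null(expr, cohort, best$spec,
                              n_reps = config$n_label_perm,
                              seed = config$seed)
  rand <- randomize_predictors_null(expr, cohort, best$spec,
                                    n_reps = config$n_pred_rand,
                                    seed = config$seed)
  for (nd in list(boot, perm, rand)) {
    write_tsv_report(data.frame(auc = nd$auc_samples),
                     file.path(config$out_dir,
                               paste0("null_", nd$kind, ".tsv")),
                     header_comment = sprintf("kind=%s seed=%d n_reps=%d",
                                              nd$kind, nd$seed, nd$n_reps))
  }
  summary_obj <- list(
    observed_auc = roc$auc,
    youden_cutoff = roc$youden_threshold,
    bootstrap_mean = boot$mean, bootstrap_sd = boot$sd,
    label_permutation_p = perm$empirical_p,
    predictor_randomization_p = rand$empirical_p,
    n_candidates_passed = n_pass,
    best_logistic_predictors = as.list(best$spec$predictors),
    best_linear_predictors = as.list(search_lin$best$spec$predictors),
    all_significant = search_log$found_all_significant,
    seed = config$seed)
  yaml::write_yaml(summary_obj, file.path(config$out_dir, "summary.yaml"),
                   precision = 15)
  logf("bootstrap AUC = ", sprintf("%.3f +/- %.3f", boot$mean, boot$sd),
       "; label-permutation p = ", sprintf("%.4g", perm$empirical_p),
       "; predictor-randomization p = ", sprintf("%.4g", rand$empirical_p))
  logf("pipeline complete")

  invisible(list(expression = expr, cohort = cohort, candidates = cand,
                 trajectory = traj,
                 search_logistic = search_log, search_linear = search_lin,
                 roc = roc, bootstrap = boot, label_permutation = perm,
                 predictor_randomization = rand, summary = summary_obj,
                 out_dir = config$out_dir))
}

# Tab-separated report with '.' decimal and 12 significant digits.
write_tsv_report <- function(df, path, header_comment = NULL) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  if (!is.null(header_comment)) {
    cat("# ", header_comment, "\n", sep = "", file = path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, dec = ".",
                                        append = TRUE))
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, dec = ".")
  }
  invisible(path)
}
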