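#' Frozen reference models for PIRA and 24-month EDSS change
#'
#' The two models reported for the reference RRMS cohort, stored verbatim
#' as data constants (they are not refit):
#'
#' * `eq1_pira` — logistic classifier of PIRA status from four baseline
#'   miRNAs (hsa-miR-4485-5p, hsa-miR-340-3p, hsa-miR-6126,
#'   hsa-miR-223-3p; two main effects and four pairwise interactions),
#'   with decision threshold 0.277 on the logistic score (maximum Youden
#'   cutoff): score >= 0.277 predicts PIRA.
#' * `eq2_edss` — multilinear model of EDSS change (T4 - T0) from
#'   hsa-miR-4466, hsa-miR-24-3p, hsa-miR-6090 and hsa-miR-223-3p (three
#'   main effects and five pairwise interactions).
#'
#' @param name `"eq1_pira"` or `"eq2_edss"`.
#' @return a `mir_fit` with `frozen = TRUE`; standard errors and Wald
#'   p-values are `NA` (the source reports all coefficients significant
#'   at 0.05 but not their SEs).
#' @examples
#' m <- reference_model("eq1_pira")
#' coef(m)[["(Intercept)"]]  # -425.78
#' @export
reference_model <- function(name = c("eq1_pira", "eq2_edss")) {
  name <- match.arg(name)
  if (name == "eq1_pira") {
    coefs <- c(
      "(Intercept)" = -425.78,
      "hsa-miR-4485-5p" = 43.66,
      "hsa-miR-340-3p" = 154.79,
      "hsa-miR-4485-5p:hsa-miR-6126" = -20.42,
      "hsa-miR-223-3p:hsa-miR-6126" = 15.46,
      "hsa-miR-340-3p:hsa-miR-6126" = 15.59,
      "hsa-miR-223-3p:hsa-miR-340-3p" = -9.49)
    spec <- model_spec(
      predictors = c("hsa-miR-4485-5p", "hsa-miR-340-3p", "hsa-miR-6126",
                     "hsa-miR-223-3p"),
      terms = names(coefs)[-1],
      family = "logistic", response = "pira")
    threshold <- 0.277
  } else {
    coefs <- c(
      "(Intercept)" = 1183.40,
      "hsa-miR-4466" = 75.06,
      "hsa-miR-24-3p" = -185.95,
      "hsa-miR-6090" = -159.92,
      "hsa-miR-223-3p:hsa-miR-4466" = 11.97,
      "hsa-miR-24-3p:hsa-miR-4466" = -23.99,
      "hsa-miR-223-3p:hsa-miR-24-3p" = 4.76,
      "hsa-miR-223-3p:hsa-miR-6090" = -14.80,
      "hsa-miR-24-3p:hsa-miR-6090" = 36.84)
    spec <- model_spec(
      predictors = c("hsa-miR-4466", "hsa-miR-24-3p", "hsa-miR-6090",
                     "hsa-miR-223-3p"),
      terms = names(coefs)[-1],
      family = "linear", response = "edss_change")
    threshold <- NULL
  }
  nm <- names(coefs)
  structure(list(
    spec = spec,
    coefficients = coefs,
    std_errors = stats::setNames(rep(NA_real_, length(coefs)), nm),
    z = stats::setNames(rep(NA_real_, length(coefs)), nm),
    wald_p = stats::setNames(rep(NA_real_, length(coefs)), nm),
    loglik = NA_real_, npar = length(coefs),
    aic = NA_real_, aicc = NA_real_, bic = NA_real_,
    converged = TRUE, separation_flag = FALSE, all_significant = TRUE,
    alpha = 0.05, n = NULL, fitted = NULL, y = NULL,
    threshold = threshold, frozen = TRUE
  ), class = "mir_fit")
}

#' Serialize / restore a fitted model as YAML
#'
#' The YAML schema (family, response, predictors, terms, coefficients,
#' optional threshold) is shared between the frozen reference constants
#' and models produced by [search_best()], so the two round-trip through
#' the same files.
#'
#' @param fit a `mir_fit`.
#' @param path output file.
#' @return `write_model_yaml` returns `path` invisibly;
#'   `read_model_yaml` returns a `mir_fit` (frozen, i.e. coefficients as
#'   stored, no refit).
#' @export
write_model_yaml <- function(fit, path) {
  stopifnot(inherits(fit, "mir_fit"))
  obj <- list(
    family = fit$spec$family,
    response = fit$spec$response,
    predictors = as.list(fit$spec$predictors),
    terms = as.list(fit$spec$terms),
    coefficients = as.list(fit$coefficients),
    threshold = fit$threshold
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  spec <- model_spec(unlist(obj$predictors), unlist(obj$terms),
                     family = obj$family, response = obj$response)
  coefs <- unlist(obj$coefficients)
  nm <- names(coefs)
  structure(list(
    spec = spec, coefficients = coefs,
    std_errors = stats::setNames(rep(NA_real_, length(coefs)), nm),
    z = stats::setNames(rep(NA_real_, length(coefs)), nm),
    wald_p = stats::setNames(rep(NA_real_, length(coefs)), nm),
    loglik = NA_real_, npar = length(coefs),
    aic = NA_real_, aicc = NA_real_, bic = NA_real_,
    converged = TRUE, separation_flag = FALSE, all_significant = TRUE,
    alpha = 0.05, n = NULL, fitted = NULL, y = NULL,
    threshold = obj$threshold, frozen = TRUE
  ), class = "mir_fit")
}
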