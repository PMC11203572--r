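# Resolve the response vector for a spec from a cohort or a plain vector.
resolve_response <- function(spec, outcome) {
  if (is.numeric(outcome) || is.integer(outcome)) return(as.numeric(outcome))
  stopifnot(is.data.frame(outcome))
  switch(spec$response,
         pira = as.numeric(outcome$pira),
         edss_change = outcome$edss_t4 - outcome$edss_t0,
         stop("unknown response: ", spec$response))
}

#' Fit a specified logistic or linear model
#'
#' Logistic models are fit by maximum likelihood (iteratively reweighted
#' least squares, deviance-converged); linear models by least squares with
#' classical standard errors.  Interaction columns are elementwise
#' products of the uncentered log2 expression vectors.  Every coefficient
#' (intercept included) gets a Wald test against zero on the normal (z)
#' reference; `wald = "t"` switches the linear family to the t reference
#' with n - p degrees of freedom.
#'
#' A fit is flagged as (quasi-)separated when it fails to converge or when
#' any |coefficient| or standard error exceeds `guard`; Wald p-values are
#' not interpretable in that regime and such fits are excluded from the
#' all-significant pool of [search_best()].
#'
#' @param spec a [model_spec()].
#' @param expr an `expr_matrix` containing the spec's predictors.
#' @param outcome a `mir_cohort` (response drawn per `spec$response`) or a
#'   numeric response vector.
#' @param alpha significance level for the all-significant flag.
#' @param guard separation guard on |coefficient| and SE (default 1e3).
#' @param wald `"z"` (default, both families) or `"t"` (linear only).
#' @param engine `"glm"` uses [stats::glm.fit()]/least squares in R;
#'   `"cpp"` uses the compiled IRLS used by the exhaustive search.  Both
#'   agree to ~1e-8 and are cross-checked in the tests.
#' @return object of class `mir_fit`.
#' @export
fit_glm <- function(spec, expr, outcome, alpha = 0.05, guard = 1e3,
                    wald = c("z", "t"), engine = c("glm", "cpp")) {
  wald <- match.arg(wald)
  engine <- match.arg(engine)
  y <- resolve_response(spec, outcome)
  X <- build_design(spec, expr)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("more terms (", p, ") than observations (", n, ")")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }

  if (engine == "cpp") {
    fam <- if (spec$family == "logistic") 0L else 1L
    f <- fit_single_cpp(X, y, fam)
    coefs <- stats::setNames(f$coef, colnames(X))
    se <- stats::setNames(f$se, colnames(X))
    loglik <- f$loglik
    npar <- f$npar
    converged <- f$ok
  } else if (spec$family == "logistic") {
    if (!all(y %in% c(0, 1))) stop("logistic response must be 0/1")
    f <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100))
    coefs <- f$coefficients
    mu <- pmin(pmax(f$fitted.values, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    cov <- tryCatch(solve(crossprod(X * sqrt(w))),
                    error = function(e) matrix(NA_real_, p, p))
    se <- stats::setNames(sqrt(diag(cov)), colnames(X))
    loglik <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    npar <- p
    converged <- isTRUE(f$converged)
  } else {
    f <- stats::lm.fit(X, y)
    coefs <- f$coefficients
    rss <- sum(f$residuals^2)
    sigma2 <- rss / (n - p)
    cov <- sigma2 * chol2inv(qr.R(qrX))
    se <- stats::setNames(sqrt(diag(cov)), colnames(X))
    loglik <- -0.5 * n * (log(2 * pi * rss / n) + 1)
    npar <- p + 1
    converged <- TRUE
  }

  z <- coefs / se
  wald_p <- if (wald == "t" && spec$family == "linear") {
    2 * stats::pt(-abs(z), df = n - p)
  } else {
    2 * stats::pnorm(-abs(z))
  }
  separation <- !converged || anyNA(coefs) || anyNA(se) ||
    max(abs(coefs)) > guard || max(se) > guard
  all_sig <- !separation && all(is.finite(wald_p)) && all(wald_p < alpha)

  structure(list(
    spec = spec,
    coefficients = coefs, std_errors = se, z = z, wald_p = wald_p,
    loglik = loglik, npar = npar,
    aic = -2 * loglik + 2 * npar,
    aicc = -2 * loglik + 2 * npar +
      if (n - npar - 1 > 0) 2 * npar * (npar + 1) / (n - npar - 1) else Inf,
    bic = -2 * loglik + log(n) * npar,
    converged = converged, separation_flag = separation,
    all_significant = all_sig,
    alpha = alpha, n = n,
    fitted = if (spec$family == "logistic")
      as.numeric(stats::plogis(X %*% coefs)) else as.numeric(X %*% coefs),
    y = y, threshold = NULL, frozen = FALSE
  ), class = "mir_fit")
}

#' Information criterion of a fitted model
#' @param fit a `mir_fit`.
#' @param criterion `"AIC"`, `"AICc"` or `"BIC"`.
#' @return the criterion value.
#' @export
model_ic <- function(fit, criterion = c("AIC", "AICc", "BIC")) {
  switch(match.arg(criterion), AIC = fit$aic, AICc = fit$aicc, BIC = fit$bic)
}

#' @export
print.mir_fit <- function(x, ...) {
  cat(sprintf("%s model (%s)%s: %d term(s) + intercept, n = %s\n",
              x$spec$family, x$spec$response,
              if (x$frozen) " [frozen reference]" else "",
              length(x$spec$terms),
              if (is.null(x$n)) "?" else x$n))
  print(round(x$coefficients, 4))
  if (!x$frozen) {
    cat(sprintf("logLik = %.3f, AIC = %.3f, all coefficients significant: %s\n",
                x$loglik, x$aic, x$all_significant))
    if (x$separation_flag) cat("WARNING: separation guard tripped\n")
  }
  if (!is.null(x$threshold)) {
    cat(sprintf("classification threshold (score >= cutoff -> positive): %.3f\n",
                x$threshold))
  }
  invisible(x)
}

#' @export
summary.mir_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients,
                    std_error = object$std_errors,
                    z = object$z, wald_p = object$wald_p)
  out <- list(table = tab, fit = object)
  class(out) <- "summary.mir_fit"
  out
}

#' @export
print.summary.mir_fit <- function(x, ...) {
  print(x$fit)
  cat("\nWald tests (H0: coefficient = 0):\n")
  print(round(x$table, 5))
  invisible(x)
}

#' @export
coef.mir_fit <- function(object, ...) object$coefficients

#' Predict scores, values, or classes from a fitted model
#'
#' Logistic models return the logistic score `exp(Z)/(1 + exp(Z))`
#' (`type = "response"`), the linear predictor Z (`type = "link"`), or the
#' thresholded class (`type = "class"`, score >= threshold -> 1); linear
#' models return the predicted EDSS change.
#'
#' @param object a `mir_fit`.
#' @param newdata an `expr_matrix` (features x samples) containing the
#'   model's predictors.
#' @param type `"response"`, `"link"` or `"class"`.
#' @param threshold classification cutoff; defaults to the model's stored
#'   threshold (e.g. 0.277 for the frozen PIRA reference model).
#' @return numeric (or integer for `"class"`) vector over samples.
#' @export
predict.mir_fit <- function(object, newdata,
                            type = c("response", "link", "class"),
                            threshold = NULL, ...) {
  type <- match.arg(type)
  X <- build_design(object$spec, newdata)
  eta <- as.numeric(X %*% object$coefficients[colnames(X)])
  names(eta) <- colnames(newdata)
  if (object$spec$family == "linear") return(eta)
  if (type == "link") return(eta)
  score <- stats::plogis(eta)
  if (type == "response") return(score)
  thr <- if (!is.null(threshold)) threshold else object$threshold
  if (is.null(thr)) stop("no classification threshold stored; supply one")
  as.integer(score >= thr)
}

#' @export
residuals.mir_fit <- function(object, ...) {
  if (object$frozen || is.null(object$y)) {
    stop("no training response stored for this model")
  }
  object$y - object$fitted
}
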