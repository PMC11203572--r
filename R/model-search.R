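#' Exhaustive significance-constrained model search
#'
#' The package's core procedure: over every `k`-subset of the candidate
#' features, every nonempty set of main-effect and pairwise-interaction
#' terms (`2^(k + choose(k,2)) - 1` term sets per subset, marginality not
#' enforced) is fit by maximum likelihood (logistic) or least squares
#' (linear).  Fits that are rank-deficient, non-converged, or trip the
#' quasi-separation guard are discarded.  Among the remaining models, the
#' requirement that every coefficient — intercept included — be Wald-
#' significant at `alpha` acts as the primary (hard) filter; the
#' information criterion only ranks the models that survive it.  When no
#' all-significant model exists, the best model by criterion is returned
#' with a prominent warning.
#'
#' Ties in the criterion are broken toward fewer terms, then by
#' lexicographic predictor order, so results are deterministic.
#'
#' @param expr an `expr_matrix` (log2-normalized) containing the
#'   candidates.
#' @param outcome a `mir_cohort`, or a numeric response vector (0/1 for
#'   the logistic family).
#' @param candidates character vector of candidate feature IDs, or a
#'   `mir_candidates` screen (its passed features are used).
#' @param k predictor-subset size (default 4).
#' @param family `"logistic"` or `"linear"`.
#' @param criterion `"AIC"` (default), `"AICc"` or `"BIC"`.
#' @param alpha Wald significance level for the all-significant filter.
#' @param guard separation guard on |coefficient| and SE.
#' @param response response name recorded in the specs; defaults by
#'   family.
#' @return object of class `mir_search` with the refit best model
#'   (`$best`, a `mir_fit`), a per-subset summary table (`$table`), and
#'   search counts.  `coef`, `predict` and `summary` delegate to the best
#'   model.
#' @export
search_best <- function(expr, outcome, candidates, k = 4,
                        family = c("logistic", "linear"),
                        criterion = c("AIC", "AICc", "BIC"),
                        alpha = 0.05, guard = 1e3, response = NULL) {
  family <- match.arg(family)
  criterion <- match.arg(criterion)
  if (inherits(candidates, "mir_candidates")) {
    candidates <- candidates$mirna_id[candidates$passed]
  }
  candidates <- as.character(candidates)
  if (length(candidates) == 0) stop("no candidate features supplied")
  if (k > length(candidates)) {
    stop("k = ", k, " exceeds the ", length(candidates),
         " available candidate(s)")
  }
  if (is.null(response)) {
    response <- if (family == "logistic") "pira" else "edss_change"
  }
  probe <- model_spec(candidates[1], candidates[1], family = family,
                      response = response)
  y <- resolve_response(probe, outcome)
  if (family == "logistic" && !all(y %in% c(0, 1))) {
    stop("logistic response must be 0/1")
  }
  v <- unclass(expr)
  fam_code <- if (family == "logistic") 0L else 1L
  pen <- function(ll, np) switch(criterion,
                                 AIC = -2 * ll + 2 * np,
                                 AICc = -2 * ll + 2 * np +
                                   2 * np * (np + 1) / pmax(length(y) - np - 1, 1e-9),
                                 BIC = -2 * ll + log(length(y)) * np)

  subsets <- utils::combn(sort(candidates), k, simplify = FALSE)
  n_models <- 0L; n_failed <- 0L; n_allsig <- 0L
  best <- NULL   # list(ic, nterms, subset_key, mask, subset)
  rows <- vector("list", length(subsets))

  for (si in seq_along(subsets)) {
    sub <- subsets[[si]]
    terms <- all_terms(sub)
    X <- vapply(terms, function(tm) {
      f <- term_features(tm)
      if (length(f) == 1) v[f, ] else v[f[1], ] * v[f[2], ]
    }, numeric(ncol(v)))
    res <- exhaustive_fit_cpp(X, y, fam_code, alpha = alpha, guard = guard)
    n_models <- n_models + nrow(res)
    ok <- res[, 3] == 1
    allsig <- res[, 4] == 1
    n_failed <- n_failed + sum(!ok)
    n_allsig <- n_allsig + sum(allsig)
    ics <- pen(res[, 1], res[, 2])
    nterms_mask <- vapply(seq_len(nrow(res)),
                          function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(length(terms) - 1L))) != 0L),
                          numeric(1))
    key <- paste(sub, collapse = "|")
    consider <- function(pool_mask) {
      idx <- which(pool_mask)
      if (!length(idx)) return(NULL)
      o <- idx[order(ics[idx], nterms_mask[idx])][1]
      list(ic = ics[o], nterms = nterms_mask[o], mask = o, subset = sub,
           key = key, allsig = allsig[o])
    }
    cand_best <- consider(allsig & is.finite(ics))
    fallback <- consider(ok & is.finite(ics))
    rows[[si]] <- data.frame(
      predictors = key,
      n_ok = sum(ok), n_allsig = sum(allsig),
      best_ic = if (!is.null(cand_best)) cand_best$ic else NA_real_,
      best_ic_any = if (!is.null(fallback)) fallback$ic else NA_real_,
      stringsAsFactors = FALSE)

    for (cb in list(cand_best, fallback)) {
      if (is.null(cb)) next
      if (is.null(best) ||
          (cb$allsig > best$allsig) ||
          (cb$allsig == best$allsig &&
             (cb$ic < best$ic - 1e-12 ||
                (abs(cb$ic - best$ic) <= 1e-12 &&
                   (cb$nterms < best$nterms ||
                      (cb$nterms == best$nterms && cb$key < best$key)))))) {
        best <- cb
      }
    }
  }

  if (is.null(best)) stop("all fits failed; no model could be ranked")
  if (!best$allsig) {
    warning("no model with all coefficients significant at alpha = ", alpha,
            " was found; returning the best model by ", criterion,
            " WITHOUT the significance guarantee")
  }
  terms <- all_terms(best$subset)
  sel <- terms[bitwAnd(best$mask, bitwShiftL(1L, seq_along(terms) - 1L)) != 0L]
  best_spec <- model_spec(best$subset, sel, family = family,
                          response = response)
  best_fit <- fit_glm(best_spec, expr, outcome, alpha = alpha, guard = guard)

  table <- do.call(rbind, rows)
  table <- table[order(table$best_ic, table$best_ic_any), , drop = FALSE]
  rownames(table) <- NULL
  structure(list(
    best = best_fit, table = table,
    n_models = n_models, n_failed = n_failed, n_allsig = n_allsig,
    n_subsets = length(subsets),
    found_all_significant = best$allsig,
    k = k, family = family, criterion = criterion, alpha = alpha,
    candidates = sort(candidates)
  ), class = "mir_search")
}

#' @export
print.mir_search <- function(x, ...) {
  cat(sprintf("exhaustive %s model search: %d candidates, k = %d\n",
              x$family, length(x$candidates), x$k))
  cat(sprintf("  %d subsets x term sets = %d models fit; %d discarded, %d all-significant\n",
              x$n_subsets, x$n_models, x$n_failed, x$n_allsig))
  if (!x$found_all_significant) {
    cat("  NOTE: no all-significant model found; best shown is by ",
        x$criterion, " only\n", sep = "")
  }
  cat("best model (", x$criterion, " = ",
      sprintf("%.3f", model_ic(x$best, x$criterion)), "):\n", sep = "")
  print(x$best)
  invisible(x)
}

#' @export
summary.mir_search <- function(object, n = 10, ...) {
  cat(sprintf("top %d predictor subsets by best all-significant %s:\n",
              n, object$criterion))
  print(utils::head(object$table, n), digits = 6)
  invisible(summary(object$best))
}

#' @export
coef.mir_search <- function(object, ...) coef(object$best)

#' @export
predict.mir_search <- function(object, newdata, ...) {
  predict(object$best, newdata, ...)
}

#' @export
plot.mir_search <- function(x, ...) {
  if (is.null(x$best$fitted)) stop("no fitted values stored")
  y <- x$best$y
  if (x$family == "logistic") {
    plot(jitter(y, 0.1), x$best$fitted,
         xlab = "observed PIRA status", ylab = "fitted logistic score",
         main = "best model: fitted scores by outcome", ...)
  } else {
    plot(y, x$best$fitted, xlab = "observed EDSS change",
         ylab = "predicted EDSS change",
         main = "best model: predicted vs observed", ...)
    abline(0, 1, lty = 2)
  }
  invisible(x)
}
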