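#' Reference candidate miRNA panel
#'
#' The nine PBMC miRNAs reported as significantly Pearson-correlated both
#' with PIRA status (0/1) and with the 24-month EDSS change (T4 - T0) in
#' the reference RRMS cohort, together with the reported correlation
#' coefficients and two-sided p-values (n = 25).  These correlations are
#' the default targets of the synthetic-cohort generator's exact mode.
#'
#' @return data.frame with columns `mirna_id`, `r_pira`, `p_pira`,
#'   `r_edss`, `p_edss`.
#' @export
reference_candidates <- function() {
  data.frame(
    mirna_id = c("hsa-miR-1973", "hsa-miR-223-3p", "hsa-miR-24-3p",
                 "hsa-miR-340-3p", "hsa-miR-424-5p", "hsa-miR-4466",
                 "hsa-miR-4485-5p", "hsa-miR-6090", "hsa-miR-6126"),
    r_pira = c(-0.439, 0.399, 0.447, 0.424, 0.449, -0.537, -0.430, -0.435, -0.430),
    p_pira = c(0.028, 0.048, 0.025, 0.035, 0.025, 0.006, 0.032, 0.030, 0.032),
    r_edss = c(-0.489, 0.481, 0.464, 0.482, 0.546, -0.507, -0.500, -0.456, -0.488),
    p_edss = c(0.013, 0.015, 0.019, 0.015, 0.005, 0.010, 0.011, 0.022, 0.013),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic-cohort
#' generator.  Defaults reproduce the reference study design: 25 RRMS
#' subjects (8 PIRA-positive, 3 RAW, 8 male), a 2549-feature miRNA panel,
#' baseline EDSS mean 2.2 (SD 1.78) and 24-month EDSS mean 2.54 (SD 1.97)
#' on the half-point grid, and the nine reference miRNAs embedded with
#' their reported correlations against PIRA and EDSS change.
#'
#' @param n_subjects number of subjects.
#' @param n_features number of miRNA features on the panel.
#' @param n_pira number of PIRA-positive subjects (deterministic count).
#' @param n_raw number of RAW subjects, drawn among the non-PIRA group.
#' @param n_male number of male subjects.
#' @param informative_spec data.frame with columns `feature_id`,
#'   `target_r_pira`, `target_r_edss`; one row per informative feature.
#'   Defaults to the nine rows of [reference_candidates()].  Use
#'   `informative_spec = NULL` for a pure-null panel.
#' @param correlation_mode `"exact"` realizes the requested sample
#'   correlations exactly (to ~1e-12); `"population"` targets them in
#'   expectation via a linear-Gaussian factor model.
#' @param edss_t0_mean,edss_t0_sd target mean/SD of baseline EDSS.
#' @param edss_t4_mean,edss_t4_sd target mean/SD of 24-month EDSS.
#' @param edss_step EDSS grid increment (0.5 points).
#' @param noise_sd per-feature SD of log2 expression.
#' @param baseline_mean center of the per-feature baseline log2 intensity
#'   distribution (feature baselines are drawn uniformly +/- 2 around it).
#' @param seed master seed; every random substream derives from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 25L,
                       n_features = 2549L,
                       n_pira = 8L,
                       n_raw = 3L,
                       n_male = 8L,
                       informative_spec = default_informative_spec(),
                       correlation_mode = c("exact", "population"),
                       edss_t0_mean = 2.2, edss_t0_sd = 1.78,
                       edss_t4_mean = 2.54, edss_t4_sd = 1.97,
                       edss_step = 0.5,
                       noise_sd = 1.0,
                       baseline_mean = 7.0,
                       seed = 1L) {
  correlation_mode <- match.arg(correlation_mode)
  if (is.null(informative_spec)) {
    informative_spec <- data.frame(feature_id = character(0),
                                   target_r_pira = numeric(0),
                                   target_r_edss = numeric(0))
  }
  stopifnot(is.data.frame(informative_spec),
            all(c("feature_id", "target_r_pira", "target_r_edss") %in%
                  names(informative_spec)))
  n_subjects <- as.integer(n_subjects)
  n_features <- as.integer(n_features)
  n_pira <- as.integer(n_pira)
  if (n_subjects < 3L) stop("need at least 3 subjects")
  if (n_pira < 0L || n_pira > n_subjects) {
    stop("n_pira must lie in [0, n_subjects]")
  }
  if (n_features < nrow(informative_spec)) {
    stop("n_features (", n_features, ") smaller than the number of ",
         "informative features (", nrow(informative_spec), ")")
  }
  r_all <- c(informative_spec$target_r_pira, informative_spec$target_r_edss)
  if (length(r_all) && any(abs(r_all) >= 1)) {
    stop("target correlations must lie strictly inside (-1, 1)")
  }
  if (edss_step <= 0) stop("edss_step must be positive")
  if (nrow(informative_spec) > 0 && n_pira %in% c(0L, n_subjects)) {
    stop("n_pira of 0 or n_subjects makes the PIRA correlation undefined; ",
         "cannot embed requested correlations")
  }
  cfg <- list(
    n_subjects = n_subjects, n_features = n_features,
    n_pira = n_pira, n_raw = as.integer(min(n_raw, n_subjects - n_pira)),
    n_male = as.integer(min(n_male, n_subjects)),
    informative_spec = informative_spec,
    correlation_mode = correlation_mode,
    edss_t0_mean = edss_t0_mean, edss_t0_sd = edss_t0_sd,
    edss_t4_mean = edss_t4_mean, edss_t4_sd = edss_t4_sd,
    edss_step = edss_step, noise_sd = noise_sd,
    baseline_mean = baseline_mean,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @describeIn sim_config The default informative-feature specification:
#'   the nine reference miRNAs with their reported (r_pira, r_edss) pairs.
#' @export
default_informative_spec <- function() {
  ref <- reference_candidates()
  data.frame(feature_id = ref$mirna_id,
             target_r_pira = ref$r_pira,
             target_r_edss = ref$r_edss,
             stringsAsFactors = FALSE)
}

# Derive a deterministic 31-bit substream seed from the master seed.
sub_seed <- function(master, idx) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 +
                as.numeric(idx) * 1000003 + 12345) %% 2147483647)
}

# Mean of a normal(mu, sd) truncated to [lo, hi].
tnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Draw from normal(mu*, sd) truncated to [lo, hi], with mu* solved so the
# truncated mean equals target_mean (inverse-CDF sampling, no rejection).
rtnorm_calibrated <- function(n, target_mean, sd, lo, hi) {
  mu <- stats::uniroot(function(m) tnorm_mean(m, sd, lo, hi) - target_mean,
                       lower = lo - 6 * sd, upper = hi + 6 * sd,
                       tol = 1e-10)$root
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}

snap_to_grid <- function(x, step) pmin(10, pmax(0, round(x / step) * step))

#' Embed exact sample correlations against two outcome vectors
#'
#' Constructs a feature vector whose realized sample Pearson correlations
#' with `y1` and `y2` equal `r1` and `r2` exactly (to numerical precision).
#' A Gram-Schmidt basis \{u1, u2\} of span\{y1, y2\} is built after
#' centering; the two correlation constraints fix the coefficients on u1
#' and u2, and the remaining variance is filled with the component of
#' `noise` orthogonal to both (and to the constant vector).
#'
#' The request is feasible iff `r1^2 + ((r2 - r1*rho)/sqrt(1-rho^2))^2 <= 1`,
#' where `rho` is the sample correlation of `y1` and `y2` — i.e. the
#' implied squared multiple correlation of the feature on (y1, y2) cannot
#' exceed 1.
#'
#' @param y1,y2 numeric outcome vectors (centered internally); must not be
#'   collinear after centering.
#' @param r1,r2 requested sample correlations, in (-1, 1).
#' @param noise optional numeric vector supplying the free directions;
#'   drawn from `seed` when `NULL`.
#' @param seed RNG seed used only when `noise` is `NULL`.
#' @return numeric vector with sample mean 0 and SD 1 realizing the
#'   requested correlations.
#' @examples
#' y1 <- rep(c(0, 1), c(17, 8))
#' y2 <- seq(-2, 2, length.out = 25)
#' x <- embed_exact_correlation(y1, y2, 0.537, 0.4, seed = 42)
#' cor(x, y1)  # 0.537 to machine precision
#' @export
embed_exact_correlation <- function(y1, y2, r1, r2, noise = NULL, seed = 1L) {
  n <- length(y1)
  if (length(y2) != n) stop("y1 and y2 must have equal length")
  if (n < 4) stop("need at least 4 observations")
  c1 <- y1 - mean(y1)
  c2 <- y2 - mean(y2)
  n1 <- sqrt(sum(c1^2)); n2 <- sqrt(sum(c2^2))
  if (n1 == 0 || n2 == 0) stop("y1/y2 constant: correlation undefined")
  u1 <- c1 / n1
  rho <- sum(u1 * c2) / n2
  w <- c2 - sum(u1 * c2) * u1
  nw <- sqrt(sum(w^2))
  if (nw / n2 < 1e-8) {
    stop("y1 and y2 are collinear after centering; two independent ",
         "correlation constraints cannot both be imposed")
  }
  u2 <- w / nw
  alpha <- r1
  beta <- (r2 - r1 * rho) / sqrt(1 - rho^2)
  g2 <- 1 - alpha^2 - beta^2
  if (g2 < -1e-12) {
    stop(sprintf(paste0(
      "infeasible correlation request: r1^2 + ((r2 - r1*rho)/sqrt(1-rho^2))^2",
      " = %.4f > 1 (rho = %.4f); the pair (r1, r2) must satisfy ",
      "r1^2 + (r2 - r1*rho)^2/(1 - rho^2) <= 1"), alpha^2 + beta^2, rho))
  }
  g2 <- max(g2, 0)
  if (g2 > 0) {
    if (is.null(noise)) {
      set.seed(as.integer(seed))
      noise <- stats::rnorm(n)
    }
    e <- noise - mean(noise)
    e <- e - sum(e * u1) * u1 - sum(e * u2) * u2
    ne <- sqrt(sum(e^2))
    if (ne < 1e-10) stop("noise vector has no component orthogonal to y1, y2")
    x <- alpha * u1 + beta * u2 + sqrt(g2) * e / ne
  } else {
    x <- alpha * u1 + beta * u2
  }
  # x has unit norm and zero mean; rescale to sample SD 1
  x * sqrt(n - 1)
}

#' Simulate a synthetic RRMS miRNA cohort
#'
#' Generates a full synthetic cohort matching the configured study design:
#' a log2-space expression matrix (all values > 0), a clinical table with
#' EDSS trajectories at months 0/6/12/18/24, relapse and
#' confirmed-disability-worsening (CDW) event dates consistent with the
#' assigned PIRA/RAW flags, and a `truth` record of requested vs realized
#' correlations for the informative features.
#'
#' PIRA and RAW counts are fixed by the configuration, not sampled.
#' Baseline EDSS is drawn from a truncated normal recalibrated so its
#' post-truncation mean equals the target, then snapped to the half-point
#' grid; per-interval EDSS increments drift upward for PIRA subjects so
#' the cohort's 24-month mean matches the target in expectation.
#' Informative features realize their target correlations with PIRA and
#' with EDSS change exactly (mode `"exact"`) or in expectation (mode
#' `"population"`).  A master seed spawns per-feature substreams, so
#' enlarging the panel does not perturb existing features.
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_cohort` with elements `expression`
#'   (an `expr_matrix`, log2 space), `clinical` (a `mir_cohort`
#'   data.frame) and `truth` (requested and realized correlations).
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 7))
#' sum(cohort$clinical$pira)  # 8 by construction
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  nf <- config$n_features
  spec <- config$informative_spec
  k <- nrow(spec)

  ## --- clinical substream -------------------------------------------------
  set.seed(sub_seed(config$seed, 0))
  pira <- integer(n)
  pira[sample.int(n, config$n_pira)] <- 1L
  raw <- integer(n)
  non_pira_idx <- which(pira == 0L)
  if (config$n_raw > 0 && length(non_pira_idx) > 0) {
    raw[sample(non_pira_idx, min(config$n_raw, length(non_pira_idx)))] <- 1L
  }
  sex <- rep("F", n)
  sex[sample.int(n, config$n_male)] <- "M"
  age <- round(stats::rnorm(n, 43, 8.9))
  dis_dur <- round(pmax(0.2, stats::rnorm(n, 9.48, 8.42)), 1)

  t0 <- snap_to_grid(
    rtnorm_calibrated(n, config$edss_t0_mean, config$edss_t0_sd, 0, 10),
    config$edss_step)

  # per-interval drift: PIRA subjects carry the whole configured T4-T0 gap
  d_total <- config$edss_t4_mean - config$edss_t0_mean
  if (config$n_pira > 0) {
    drift <- ifelse(pira == 1L, n * d_total / (4 * config$n_pira), 0)
  } else {
    drift <- rep(d_total / 4, n)
  }
  # per-interval increment SD chosen so Var(T4) ~ target, accounting for
  # the between-group mean split
  p <- config$n_pira / n
  delta <- if (config$n_pira > 0) n * d_total / config$n_pira else 0
  v_inc <- (config$edss_t4_sd^2 - config$edss_t0_sd^2 -
              p * (1 - p) * delta^2) / 4
  sd_inc <- sqrt(max(v_inc, 0.01))
  lat <- matrix(0, n, 5)
  lat[, 1] <- t0
  for (j in 2:5) {
    lat[, j] <- pmin(10, pmax(0, lat[, j - 1] +
                                stats::rnorm(n, drift, sd_inc)))
  }
  edss <- apply(lat, 2, snap_to_grid, step = config$edss_step)
  edss[, 1] <- t0

  baseline_date <- as.Date("2021-01-01")
  visit_days <- c(0L, 182L, 365L, 547L, 730L)
  relapse_onsets <- vector("list", n)
  cdw_events <- vector("list", n)
  pre_relapse <- sample.int(n, min(22L, n))
  for (i in seq_len(n)) {
    rel <- as.Date(character(0))
    if (i %in% pre_relapse) {
      rel <- baseline_date - sample(30:365, 1)
    }
    cdw <- as.Date(character(0))
    if (pira[i] == 1L) {
      # CDW at the month-12 or month-18 visit; any relapse is pre-baseline,
      # hence > 90 days before onset
      cdw <- baseline_date + sample(visit_days[3:4], 1)
    } else if (raw[i] == 1L) {
      r0 <- baseline_date + sample(60:400, 1)
      rel <- sort(c(rel, r0))
      cdw <- r0 + sample(0:90, 1)
    }
    relapse_onsets[[i]] <- rel
    cdw_events[[i]] <- cdw
  }

  clinical <- data.frame(
    subject_id = sprintf("subject_%02d", seq_len(n)),
    sex = sex, age = age, disease_duration = dis_dur,
    edss_t0 = edss[, 1], edss_t1 = edss[, 2], edss_t2 = edss[, 3],
    edss_t3 = edss[, 4], edss_t4 = edss[, 5],
    pira = pira, raw = raw,
    stringsAsFactors = FALSE
  )
  clinical$relapse_onsets <- relapse_onsets
  clinical$cdw_events <- cdw_events
  class(clinical) <- c("mir_cohort", "data.frame")

  ## --- expression ---------------------------------------------------------
  set.seed(sub_seed(config$seed, 1))
  mu <- stats::runif(nf, config$baseline_mean - 2, config$baseline_mean + 2)
  set.seed(sub_seed(config$seed, 2))
  # byrow fill: feature i consumes draws (i-1)*n+1 .. i*n, so enlarging the
  # panel appends new features without perturbing existing ones
  vals <- mu + config$noise_sd *
    matrix(stats::rnorm(nf * n), nrow = nf, byrow = TRUE)

  edss_change <- edss[, 5] - edss[, 1]
  realized_pira <- realized_edss <- rep(NA_real_, k)
  if (k > 0) {
    for (j in seq_len(k)) {
      fseed <- sub_seed(config$seed, 100000 + j)
      set.seed(fseed)
      noise <- stats::rnorm(n)
      if (config$correlation_mode == "exact") {
        x <- embed_exact_correlation(pira, edss_change,
                                     spec$target_r_pira[j],
                                     spec$target_r_edss[j],
                                     noise = noise)
      } else {
        x <- embed_population_correlation(pira, edss_change,
                                          spec$target_r_pira[j],
                                          spec$target_r_edss[j],
                                          noise = noise)
      }
      vals[j, ] <- mu[j] + config$noise_sd * x
      realized_pira[j] <- stats::cor(vals[j, ], pira)
      realized_edss[j] <- stats::cor(vals[j, ], edss_change)
    }
  }
  # enforce strict positivity (log2 space) without touching correlations
  row_min <- apply(vals, 1, min)
  fix <- which(row_min <= 0)
  if (length(fix)) vals[fix, ] <- vals[fix, ] - row_min[fix] + 0.5

  feature_ids <- sprintf("miR-syn-%04d", seq_len(nf))
  if (k > 0) feature_ids[seq_len(k)] <- spec$feature_id
  expr <- expression_matrix(vals, feature_ids = feature_ids,
                            sample_ids = clinical$subject_id,
                            space = "log2_normalized")

  truth <- cbind(spec,
                 realized_r_pira = realized_pira,
                 realized_r_edss = realized_edss)
  out <- list(expression = expr, clinical = clinical, truth = truth,
              config = config)
  class(out) <- "synthetic_cohort"
  out
}

# Population-mode embedding: linear-Gaussian factor model whose expected
# sample correlations equal the targets; realized values vary by sampling.
embed_population_correlation <- function(y1, y2, r1, r2, noise) {
  n <- length(y1)
  z1 <- as.numeric(scale(y1))
  resid2 <- stats::residuals(stats::lm(y2 ~ y1))
  z2 <- as.numeric(scale(resid2))
  rho <- stats::cor(y1, y2)
  alpha <- r1
  beta <- (r2 - r1 * rho) / sqrt(1 - rho^2)
  g2 <- max(0, 1 - alpha^2 - beta^2)
  x <- alpha * z1 + beta * z2 + sqrt(g2) * noise
  as.numeric(scale(x))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cl <- x$clinical
  cat(sprintf("synthetic RRMS cohort: %d subjects (%d PIRA+, %d RAW), %d miRNA features\n",
              nrow(cl), sum(cl$pira), sum(cl$raw), nrow(x$expression)))
  cat(sprintf("EDSS mean T0 = %.2f, T4 = %.2f; %d informative feature(s), mode '%s'\n",
              mean(cl$edss_t0), mean(cl$edss_t4), nrow(x$truth),
              x$config$correlation_mode))
  invisible(x)
}

#' Simulate a cohort with a known logistic generating model
#'
#' Recovery-benchmark generator: PIRA status is drawn from a logistic model
#' on a known set of predictor features (main effects with strong
#' coefficients), alongside correlated decoy features and an optional
#' block of independent null features.  Used to measure whether the
#' exhaustive model search recovers the generating predictor set.
#'
#' @param n number of subjects.
#' @param n_true number of true predictors.
#' @param n_decoys number of decoys, each correlated `decoy_cor` with one
#'   true predictor.
#' @param n_null additional independent null features.
#' @param beta coefficient shared by the true main effects.
#' @param intercept intercept of the generating model.
#' @param decoy_cor correlation between each decoy and its true partner.
#' @param seed RNG seed.
#' @return list with `expression` (an `expr_matrix`), `pira` (0/1 vector)
#'   and `true_features` (character).
#' @export
simulate_recovery_cohort <- function(n = 200L, n_true = 4L, n_decoys = 5L,
                                     n_null = 0L, beta = 2.0,
                                     intercept = -1.0, decoy_cor = 0.5,
                                     seed = 1L) {
  set.seed(as.integer(seed))
  xt <- matrix(stats::rnorm(n * n_true), n, n_true)
  xd <- matrix(0, n, n_decoys)
  for (j in seq_len(n_decoys)) {
    partner <- ((j - 1L) %% n_true) + 1L
    xd[, j] <- decoy_cor * xt[, partner] +
      sqrt(1 - decoy_cor^2) * stats::rnorm(n)
  }
  xn <- if (n_null > 0) matrix(stats::rnorm(n * n_null), n, n_null) else NULL
  eta <- intercept + xt %*% rep(beta, n_true)
  pira <- stats::rbinom(n, 1, 1 / (1 + exp(-eta)))
  vals <- t(cbind(xt, xd, xn)) + 8  # shift into positive log2-like range
  ids <- c(sprintf("true-%02d", seq_len(n_true)),
           sprintf("decoy-%02d", seq_len(n_decoys)),
           if (n_null > 0) sprintf("null-%03d", seq_len(n_null)))
  expr <- expression_matrix(vals, feature_ids = ids,
                            sample_ids = sprintf("subject_%03d", seq_len(n)),
                            space = "log2_normalized")
  list(expression = expr, pira = as.integer(pira),
       true_features = ids[seq_len(n_true)])
}
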