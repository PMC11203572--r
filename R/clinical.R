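#' Detect confirmed and sustained disability worsening (CDW) events
#'
#' Scans an EDSS series on the visit grid for worsening events.  The
#' reference EDSS at each visit is the rolling minimum of all prior
#' observations; a visit qualifies when the increase over the reference
#' meets the baseline-dependent threshold (>= 1.5 points from reference 0,
#' >= 1.0 from reference <= 5.5, >= 0.5 above 5.5) and persists at every
#' subsequent observed visit, with at least one confirming visit
#' `confirm_gap` months or more later.  Consecutive qualifying visits are
#' collapsed into a single event whose onset is the first of the run.
#'
#' @param edss_series numeric EDSS values in visit order.
#' @param times numeric visit times in months (default 0, 6, ..).
#' @param confirm_gap months required between onset and the confirming
#'   visit (default 3; on a 6-month grid any later visit confirms).
#' @return integer vector of onset indices into `edss_series` (possibly
#'   empty), with the onset times in months as names.
#' @examples
#' detect_cdw(c(2.0, 2.0, 3.0, 3.0, 3.0))  # event at visit 3
#' detect_cdw(c(2.0, 3.0, 2.0, 2.0, 2.0))  # none: not sustained
#' @export
detect_cdw <- function(edss_series,
                       times = seq(0, by = 6, length.out = length(edss_series)),
                       confirm_gap = 3) {
  n <- length(edss_series)
  if (n < 2) stop("need at least 2 observed time points")
  if (length(times) != n) stop("times must match edss_series in length")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("time points must be strictly increasing")
  }
  thr <- function(ref) if (ref == 0) 1.5 else if (ref <= 5.5) 1.0 else 0.5
  qualifies <- logical(n)
  for (t in 2:n) {
    ref <- min(edss_series[seq_len(t - 1)])
    if (edss_series[t] - ref < thr(ref)) next
    later <- seq_len(n) > t
    confirm <- later & (times - times[t] >= confirm_gap)
    if (!any(confirm)) next                       # unconfirmable (end of series)
    sustained <- all(edss_series[later] - ref >= thr(ref))
    qualifies[t] <- sustained && all(edss_series[confirm] - ref >= thr(ref))
  }
  onset <- which(qualifies & !c(FALSE, qualifies[-n]))
  names(onset) <- times[onset]
  onset
}

#' Label PIRA and RAW from CDW and relapse events
#'
#' Classifies each confirmed-disability-worsening event: RAW
#' (relapse-associated worsening) when some relapse onset lies within
#' `window_days` before (or on the day of) the event onset, PIRA
#' (progression independent of relapse activity) otherwise — i.e. when no
#' relapse precedes the event, or the closest preceding relapse started
#' more than `window_days` earlier.  Subject-level flags are the OR over
#' events; a subject with no CDW events gets `pira = 0, raw = 0`.
#'
#' An event exactly `window_days` after a relapse counts as RAW (closed
#' interval), since PIRA requires strictly more than the window.
#'
#' @param cdw_events vector of CDW onset dates (`Date`), or a list-carrying
#'   subject row from a `mir_cohort`.
#' @param relapse_onsets vector of relapse onset dates (`Date`).
#' @param window_days relapse-association window in days (default 90).
#' @return named integer vector `c(pira = 0/1, raw = 0/1)`.
#' @examples
#' base <- as.Date("2021-01-01")
#' label_progression(base + 60, base)    # raw = 1
#' label_progression(base + 120, base)   # pira = 1
#' label_progression(base + 120, as.Date(character(0)))  # pira = 1
#' @export
label_progression <- function(cdw_events, relapse_onsets = NULL,
                              window_days = 90) {
  if (is.list(cdw_events) && !is.null(cdw_events$cdw_events)) {
    relapse_onsets <- cdw_events$relapse_onsets[[1]]
    cdw_events <- cdw_events$cdw_events[[1]]
  }
  cdw_events <- as.Date(cdw_events)
  relapse_onsets <- if (is.null(relapse_onsets)) as.Date(character(0)) else
    as.Date(relapse_onsets)
  if (anyNA(cdw_events) || anyNA(relapse_onsets)) {
    stop("events present but not datable (NA dates)")
  }
  pira <- 0L; raw <- 0L
  for (ev in as.list(cdw_events)) {
    lag <- as.numeric(ev - relapse_onsets)
    if (any(lag >= 0 & lag <= window_days)) raw <- 1L else pira <- 1L
  }
  c(pira = pira, raw = raw)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact inference by full enumeration of all `choose(n_a + n_b, n_a)`
#' group assignments when the pooled sample size is at most 12 (the
#' enumeration handles ties naturally); otherwise the tie-corrected normal
#' approximation of [stats::wilcox.test()].  U is reported for the first
#' sample, so swapping the samples maps U to `n_a * n_b - U` with the same
#' p-value.
#'
#' @param a,b numeric samples (nonempty).
#' @param exact_max pooled-size limit for the enumeration path.
#' @return list with `U` and two-sided `p`.
#' @examples
#' mann_whitney_two_sided(c(1, 2, 3), c(10, 11, 12))  # p = 0.1
#' @export
mann_whitney_two_sided <- function(a, b, exact_max = 12L) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b)
  u_stat <- function(xa, xb) {
    d <- outer(xa, xb, `-`)
    sum(d > 0) + 0.5 * sum(d == 0)
  }
  u <- u_stat(a, b)
  if (na + nb <= exact_max) {
    pool <- c(a, b)
    idx <- utils::combn(na + nb, na)
    mid <- na * nb / 2
    dev_obs <- abs(u - mid)
    devs <- apply(idx, 2, function(ia) {
      abs(u_stat(pool[ia], pool[-ia]) - mid)
    })
    p <- mean(devs >= dev_obs - 1e-12)
  } else {
    p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }
  list(U = u, p = p)
}

#' EDSS trajectory comparison by PIRA group
#'
#' Per visit, group means and SDs of EDSS by PIRA status with a two-sided
#' Mann-Whitney comparison, plus a final row comparing the 24-month change
#' (T4 - T0) between groups.
#'
#' @param cohort a `mir_cohort` data.frame with `pira` and `edss_t*`
#'   columns.
#' @param time_points which EDSS columns to compare.
#' @return data.frame with one row per time point (plus `T4-T0`), columns
#'   `time`, `mean_pira`, `sd_pira`, `mean_nopira`, `sd_nopira`, `U`, `p`.
#' @export
edss_trajectory_report <- function(cohort,
                                   time_points = c("edss_t0", "edss_t1",
                                                   "edss_t2", "edss_t3",
                                                   "edss_t4")) {
  stopifnot(is.data.frame(cohort), "pira" %in% names(cohort))
  time_points <- intersect(time_points, names(cohort))
  if (length(time_points) == 0) stop("no EDSS columns found")
  g1 <- cohort$pira == 1
  if (all(g1) || !any(g1)) stop("one PIRA group is empty")
  one_row <- function(label, v) {
    mw <- mann_whitney_two_sided(v[g1], v[!g1])
    data.frame(time = label,
               mean_pira = mean(v[g1]), sd_pira = stats::sd(v[g1]),
               mean_nopira = mean(v[!g1]), sd_nopira = stats::sd(v[!g1]),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  }
  rows <- lapply(time_points, function(tp) one_row(tp, cohort[[tp]]))
  if (all(c("edss_t0", "edss_t4") %in% names(cohort))) {
    rows <- c(rows, list(one_row("T4-T0",
                                 cohort$edss_t4 - cohort$edss_t0)))
  }
  do.call(rbind, rows)
}
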