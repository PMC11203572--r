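test_that("CDW detection follows the confirmed-and-sustained rule", {
  # 1.0-point rise at visit 3, sustained to the end -> one event there
  expect_equal(unname(detect_cdw(c(2.0, 2.0, 3.0, 3.0, 3.0))), 3L)
  # transient rise is not sustained
  expect_length(detect_cdw(c(2.0, 3.0, 2.0, 2.0, 2.0)), 0)
  # above reference 5.5 the threshold drops to 0.5
  expect_equal(unname(detect_cdw(c(6.0, 6.5, 6.5, 6.5, 6.5))), 2L)
  # from reference 5.5 or below, 0.5 is not enough
  expect_length(detect_cdw(c(5.5, 6.0, 6.0, 6.0, 6.0)), 0)
  # from reference 0 the threshold is 1.5
  expect_length(detect_cdw(c(0, 1.0, 1.0, 1.0, 1.0)), 0)
  expect_equal(unname(detect_cdw(c(0, 1.5, 1.5, 1.5, 1.5))), 2L)
  # a rise at the last visit can never be confirmed
  expect_length(detect_cdw(c(2.0, 2.0, 2.0, 2.0, 4.0)), 0)
  expect_error(detect_cdw(c(2.0, 3.0), times = c(6, 0)), "increasing")
})

test_that("PIRA/RAW labelling honours the 90-day relapse window", {
  base <- as.Date("2021-03-01")
  expect_equal(label_progression(base + 60, base), c(pira = 0L, raw = 1L))
  expect_equal(label_progression(base + 120, base), c(pira = 1L, raw = 0L))
  expect_equal(label_progression(base + 120, as.Date(character(0))),
               c(pira = 1L, raw = 0L))
  # boundary: exactly 90 days counts as RAW (closed interval)
  expect_equal(label_progression(base + 90, base), c(pira = 0L, raw = 1L))
  expect_equal(label_progression(base + 91, base), c(pira = 1L, raw = 0L))
  # relapse after the event does not make it RAW
  expect_equal(label_progression(base, base + 30), c(pira = 1L, raw = 0L))
  # no CDW events: no progression labels at all
  expect_equal(label_progression(as.Date(character(0)), base),
               c(pira = 0L, raw = 0L))
  # window 0: only same-day events are RAW
  expect_equal(label_progression(base, base, window_days = 0),
               c(pira = 0L, raw = 1L))
  expect_equal(label_progression(base + 1, base, window_days = 0),
               c(pira = 1L, raw = 0L))
  # multiple events OR together
  expect_equal(label_progression(c(base + 10, base + 200), base),
               c(pira = 1L, raw = 1L))
})

test_that("Mann-Whitney exact enumeration reproduces textbook cases", {
  res <- mann_whitney_two_sided(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)  # 2 / choose(6, 3) extreme assignments
  # identical samples: U at its null mean, p = 1 under enumeration
  expect_equal(mann_whitney_two_sided(c(1, 2, 3), c(1, 2, 3))$p, 1)
})

test_that("Mann-Whitney is symmetric and agrees with the reference large-sample test", {
  set.seed(9)
  for (rep in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), 0.5)
    r1 <- mann_whitney_two_sided(a, b)
    r2 <- mann_whitney_two_sided(b, a)
    expect_equal(r1$U + r2$U, length(a) * length(b))
    expect_equal(r1$p, r2$p)
  }
  a <- rnorm(20); b <- rnorm(15, 0.3)
  got <- mann_whitney_two_sided(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_error(mann_whitney_two_sided(numeric(0), 1), "nonempty")
})

test_that("EDSS trajectory report compares groups per visit and for the T4-T0 change", {
  co <- toy_cohort(pira = c(1, 1, 1, 0, 0, 0, 0),
                   edss_t0 = c(2, 2.5, 2, 2, 2.5, 2, 2.5),
                   edss_t4 = c(4, 4.5, 5, 2, 2.5, 2, 2.5))
  rep <- edss_trajectory_report(co)
  expect_equal(rep$time, c("edss_t0", "edss_t1", "edss_t2", "edss_t3",
                           "edss_t4", "T4-T0"))
  # same T0 distribution in both groups: no evidence of a difference
  expect_gt(rep$p[rep$time == "edss_t0"], 0.5)
  # T4-T0 fully separated: smallest attainable enumeration p
  expect_lt(rep$p[rep$time == "T4-T0"], 0.06)
  expect_gt(rep$mean_pira[rep$time == "T4-T0"],
            rep$mean_nopira[rep$time == "T4-T0"])
  expect_error(edss_trajectory_report(toy_cohort(c(1, 1), c(2, 2), c(3, 3))),
               "empty")
})
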