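test_that("default cohort reproduces the study design deterministically", {
  co <- simulate_cohort(sim_config(seed = 42))
  expect_equal(nrow(co$clinical), 25)
  expect_equal(sum(co$clinical$pira), 8)
  expect_equal(sum(co$clinical$raw), 3)
  expect_equal(sum(co$clinical$sex == "M"), 8)
  expect_equal(dim(co$expression), c(2549L, 25L))
  expect_true(all(unclass(co$expression) > 0))
  expect_true(all(co$clinical$edss_t0 %% 0.5 == 0))
  expect_true(all(co$clinical$edss_t4 >= 0 & co$clinical$edss_t4 <= 10))
})

test_that("same seed gives bit-identical cohorts; different seeds differ only in noise", {
  a <- simulate_cohort(sim_config(n_features = 30, seed = 5))
  b <- simulate_cohort(sim_config(n_features = 30, seed = 5))
  expect_identical(unclass(a$expression), unclass(b$expression))
  expect_identical(a$clinical$edss_t4, b$clinical$edss_t4)

  c2 <- simulate_cohort(sim_config(n_features = 30, seed = 6))
  expect_false(identical(unclass(a$expression), unclass(c2$expression)))
  expect_equal(sum(c2$clinical$pira), sum(a$clinical$pira))
  expect_identical(dim(c2$expression), dim(a$expression))
})

test_that("enlarging the panel does not perturb existing features", {
  a <- simulate_cohort(sim_config(n_features = 40, seed = 8))
  b <- simulate_cohort(sim_config(n_features = 80, seed = 8))
  expect_identical(unclass(a$expression)[1:40, ], unclass(b$expression)[1:40, ])
})

test_that("exact mode realizes requested correlations to 1e-10 (independent oracle)", {
  co <- simulate_cohort(sim_config(n_features = 9, seed = 31))
  spec <- co$config$informative_spec
  pira <- co$clinical$pira
  dedss <- co$clinical$edss_t4 - co$clinical$edss_t0
  for (j in seq_len(nrow(spec))) {
    x <- unclass(co$expression)[spec$feature_id[j], ]
    expect_equal(oracle_pearson(x, pira)$r, spec$target_r_pira[j],
                 tolerance = 1e-10)
    expect_equal(oracle_pearson(x, dedss)$r, spec$target_r_edss[j],
                 tolerance = 1e-10)
  }
})

test_that("exact-correlation embedding satisfies constraints over random feasible requests", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(15:60, 1)
    y1 <- rbinom(n, 1, 0.4)
    if (length(unique(y1)) < 2) next
    y2 <- 0.6 * y1 + rnorm(n)
    rho <- cor(y1, y2)
    r1 <- runif(1, -0.7, 0.7)
    # draw r2 inside the feasible ellipse
    width <- sqrt(max(0, (1 - r1^2) * (1 - rho^2))) * 0.95
    r2 <- r1 * rho + runif(1, -width, width)
    x <- embed_exact_correlation(y1, y2, r1, r2, seed = rep)
    expect_equal(oracle_pearson(x, y1)$r, r1, tolerance = 1e-10)
    expect_equal(oracle_pearson(x, y2)$r, r2, tolerance = 1e-10)
    expect_equal(mean(x), 0, tolerance = 1e-12)
    expect_equal(sd(x), 1, tolerance = 1e-10)
  }
})

test_that("embedding edge cases: zero targets, collinearity, infeasibility", {
  y1 <- rep(c(0, 1), c(10, 6))
  y2 <- seq_len(16) + c(0.3, -0.2)
  x0 <- embed_exact_correlation(y1, y2, 0, 0, seed = 2)
  expect_equal(abs(cor(x0, y1)), 0, tolerance = 1e-10)
  expect_equal(abs(cor(x0, y2)), 0, tolerance = 1e-10)

  expect_error(embed_exact_correlation(y1, y1, 0.99, 0.1, seed = 1),
               "collinear")
  # rho ~ 0 here, so r1^2 + r2^2 > 1 is infeasible
  y3 <- embed_exact_correlation(y1, y2, 0, 0, seed = 3)  # orthogonal to y1
  expect_error(embed_exact_correlation(y1, y3, 0.9, 0.9, seed = 4),
               "infeasible")
})

test_that("constant PIRA with requested correlations is rejected", {
  expect_error(sim_config(n_pira = 0), "undefined")
  expect_error(sim_config(n_pira = 25), "undefined")
  # but a pure-null panel with extreme splits is fine
  cfg <- sim_config(n_pira = 0, informative_spec = NULL, n_features = 5)
  expect_s3_class(cfg, "sim_config")
})

test_that("null features behave as nulls: p-values vs PIRA approximately uniform", {
  ps <- unlist(lapply(1:6, function(s) {
    co <- simulate_cohort(sim_config(n_features = 150,
                                     informative_spec = NULL, seed = s))
    pira <- co$clinical$pira
    apply(unclass(co$expression), 1,
          function(x) oracle_pearson(x, pira)$p)
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.02)
})

test_that("generated event dates reproduce the assigned PIRA/RAW flags", {
  for (s in 1:3) {
    co <- simulate_cohort(sim_config(n_features = 9, seed = s))
    cl <- co$clinical
    derived <- t(vapply(seq_len(nrow(cl)), function(i) {
      label_progression(cl$cdw_events[[i]], cl$relapse_onsets[[i]])
    }, c(pira = 0L, raw = 0L)))
    expect_equal(unname(derived[, "pira"]), cl$pira)
    expect_equal(unname(derived[, "raw"]), cl$raw)
  }
})

test_that("population mode hits targets in expectation, not exactly", {
  spec <- data.frame(feature_id = "f1", target_r_pira = 0.5,
                     target_r_edss = 0.45)
  rs <- vapply(1:60, function(s) {
    co <- simulate_cohort(sim_config(n_features = 1, informative_spec = spec,
                                     correlation_mode = "population",
                                     seed = s))
    cor(unclass(co$expression)[1, ], co$clinical$pira)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.07)
  expect_gt(sd(rs), 0.01)  # genuinely stochastic
})

test_that("PIRA group drifts upward: positive expected T4-T0 separation", {
  diffs <- vapply(1:10, function(s) {
    cl <- simulate_cohort(sim_config(n_features = 9, seed = s))$clinical
    d <- cl$edss_t4 - cl$edss_t0
    mean(d[cl$pira == 1]) - mean(d[cl$pira == 0])
  }, numeric(1))
  expect_gt(mean(diffs), 0.5)
})
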