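# Shared fixture: small informative cohort and a 2-main-effect spec on it.
informative_fixture <- function() {
  co <- small_sim(seed = 3, n_features = 40)
  spec <- model_spec(c("hsa-miR-4466", "hsa-miR-424-5p"),
                     family = "logistic")
  list(co = co, spec = spec)
}

test_that("bootstrap AUC is reproducible and reflects refitting optimism", {
  fx <- informative_fixture()
  b1 <- bootstrap_auc(fx$co$expression, fx$co$clinical, fx$spec,
                      n_reps = 60, seed = 5)
  b2 <- bootstrap_auc(fx$co$expression, fx$co$clinical, fx$spec,
                      n_reps = 60, seed = 5)
  expect_identical(b1$auc_samples, b2$auc_samples)
  expect_true(all(b1$auc_samples >= 0 & b1$auc_samples <= 1))
  expect_true(is.na(b1$empirical_p))      # bootstrap reports mean +/- SD only
  # optimism of refitting: bootstrap mean does not fall far below apparent
  expect_gte(b1$mean, b1$observed_auc - 0.05)

  single <- bootstrap_auc(fx$co$expression, fx$co$clinical, fx$spec,
                          n_reps = 1, seed = 7)
  expect_length(single$auc_samples, 1)
})

test_that("label-permutation null: empirical p uses the add-one rule and is bounded below", {
  fx <- informative_fixture()
  perm <- permute_labels_null(fx$co$expression, fx$co$clinical, fx$spec,
                              n_reps = 99, seed = 11)
  expect_gte(perm$empirical_p, 1 / 100)   # attainable minimum with 99 reps
  expect_equal(perm$empirical_p,
               (1 + sum(perm$auc_samples >= perm$observed_auc)) / 100)
  # refit on permuted labels still overfits: null mean above 0.5
  expect_gte(perm$mean, 0.5)
  # strongly informative cohort: observed AUC beats essentially all permutations
  expect_lte(perm$empirical_p, 0.05)
})

test_that("predictor randomization substitutes positionally and validates the pool", {
  fx <- informative_fixture()
  expect_error(
    randomize_predictors_null(fx$co$expression, fx$co$clinical, fx$spec,
                              pool = fx$spec$predictors, n_reps = 5,
                              seed = 1),
    "pool too small")
  rnd <- randomize_predictors_null(fx$co$expression, fx$co$clinical, fx$spec,
                                   n_reps = 60, seed = 13)
  rnd2 <- randomize_predictors_null(fx$co$expression, fx$co$clinical,
                                    fx$spec, n_reps = 60, seed = 13)
  expect_identical(rnd$auc_samples, rnd2$auc_samples)
  # informative observed model vs mostly-null pool: small empirical p
  expect_lte(rnd$empirical_p, 0.1)
  expect_true(all(rnd$auc_samples >= 0 & rnd$auc_samples <= 1))
})

test_that("reference classifier evaluation scores, classifies at 0.277, and bounds scores", {
  feats <- reference_model("eq1_pira")$spec$predictors
  set.seed(41)
  # cohort constructed so the frozen model separates the groups with
  # moderate |Z|: hold three features near-constant and drive Z through
  # the miR-340-3p main effect (+154.79 per unit)
  pira <- rep(c(0L, 1L), c(17, 8))
  vals <- matrix(0.01, 4, 25, dimnames = list(feats, NULL))
  vals["hsa-miR-4485-5p", ] <- 9
  vals["hsa-miR-340-3p", ] <- ifelse(pira == 1, 0.30, 0.05) +
    runif(25, 0, 0.01)
  expr <- toy_expr(vals, feature_ids = feats)
  out <- evaluate_reference_classifier(expr, toy_cohort(pira, rep(2, 25),
                                                        rep(2, 25)))
  expect_equal(out$threshold, 0.277)
  expect_equal(out$roc$auc, 1)
  expect_true(all(out$scores > 0 & out$scores < 1))
  expect_equal(out$classes, as.integer(out$scores >= 0.277))
  expect_error(evaluate_reference_classifier(
    toy_expr(matrix(1, 1, 2), feature_ids = "x"), c(0L, 1L)), "missing")
})
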