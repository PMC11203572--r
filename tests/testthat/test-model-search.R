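test_that("term-set enumeration matches the combinatorial count and a brute-force oracle", {
  expect_length(enumerate_models(c("a", "b"), k = 2), 7)           # 2^3 - 1
  expect_equal(count_term_sets(4), 1023)                           # 2^10 - 1
  expect_equal(choose(9, 4) * count_term_sets(4), 128898)
  expect_length(enumerate_models("a", k = 1), 1)                   # main only

  # brute-force oracle: independent nested enumeration over 3 candidates, k = 2
  cands <- c("x", "y", "z")
  oracle <- character(0)
  for (i in 1:2) for (j in (i + 1):3) {
    pair <- cands[c(i, j)]
    terms <- c(pair, paste(sort(pair), collapse = ":"))
    for (m in 1:7) {
      sel <- terms[as.logical(bitwAnd(m, c(1L, 2L, 4L)))]
      oracle <- c(oracle, paste(sort(sel), collapse = "+"))
    }
  }
  got <- vapply(enumerate_models(cands, k = 2),
                function(s) paste(sort(s$terms), collapse = "+"),
                character(1))
  expect_setequal(got, oracle)
  expect_equal(length(got), length(oracle))

  expect_error(enumerate_models(cands, k = 0), "positive")
  expect_error(model_spec(c("a", "b"), c("a", "a")), "duplicate")
  expect_error(model_spec("a", "a:a"), "distinct")
  expect_error(model_spec("a", "a:b"), "outside")
})

test_that("linear fit recovers a noiseless relationship exactly", {
  x <- seq(1, 3, length.out = 20)
  expr <- toy_expr(matrix(x, 1), feature_ids = "g")
  fit <- fit_glm(model_spec("g", family = "linear"), expr, 2 * x)
  expect_equal(unname(coef(fit)["g"]), 2, tolerance = 1e-10)
  expect_lt(fit$std_errors["g"], 1e-8)
  expect_lt(fit$wald_p["g"], 1e-10)
})

test_that("logistic fit on a separable toy trips the separation guard", {
  x <- c(1:10, 21:30)
  y <- rep(c(0, 1), each = 10)
  expr <- toy_expr(matrix(x, 1), feature_ids = "g")
  fit <- suppressWarnings(   # glm itself warns of fitted 0/1 probabilities
    fit_glm(model_spec("g", family = "logistic"), expr, y))
  expect_true(fit$separation_flag)
  expect_false(fit$all_significant)
})

test_that("logistic MLE agrees with a generic optimizer to 1e-6", {
  set.seed(33)
  n <- 50
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- -0.5 + 1.2 * x1 - 0.8 * x2
  y <- rbinom(n, 1, plogis(eta))
  expr <- toy_expr(rbind(x1, x2), feature_ids = c("g1", "g2"))
  spec <- model_spec(c("g1", "g2"), family = "logistic")
  fit <- fit_glm(spec, expr, y)
  nll <- function(b) {
    e <- b[1] + b[2] * x1 + b[3] * x2
    -sum(y * e - log1p(exp(e)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-6)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-8)
})

test_that("compiled fitter agrees with the reference R fit for both families", {
  set.seed(14)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n)
  expr <- toy_expr(rbind(x1, x2), feature_ids = c("g1", "g2"))
  yb <- rbinom(n, 1, plogis(0.5 * x1 - 0.5 * x2))
  yc <- 1 + x1 - 2 * x2 + rnorm(n)
  for (case in list(list("logistic", yb), list("linear", yc))) {
    spec <- model_spec(c("g1", "g2"), c("g1", "g2", "g1:g2"),
                       family = case[[1]])
    a <- fit_glm(spec, expr, case[[2]], engine = "glm")
    b <- fit_glm(spec, expr, case[[2]], engine = "cpp")
    expect_equal(coef(a), coef(b), tolerance = 1e-8)
    expect_equal(a$std_errors, b$std_errors, tolerance = 1e-7)
    expect_equal(a$loglik, b$loglik, tolerance = 1e-8)
    expect_equal(a$aic, b$aic, tolerance = 1e-7)
  }
})

test_that("rank-deficient designs are rejected naming the collinear terms", {
  x <- rnorm(20)
  expr <- toy_expr(rbind(x, 2 * x), feature_ids = c("g1", "g2"))
  expect_error(fit_glm(model_spec(c("g1", "g2"), family = "linear"),
                       expr, rnorm(20)),
               "collinear")
})

test_that("exhaustive search equals a brute-force re-enumeration on a tiny instance", {
  set.seed(51)
  n <- 40
  v <- matrix(rnorm(3 * n), 3)
  expr <- toy_expr(v, feature_ids = c("x", "y", "z"))
  yb <- rbinom(n, 1, plogis(-0.3 + 1.5 * v[1, ] + v[2, ]))
  got <- suppressWarnings(   # with this draw the fallback path is in play
    search_best(expr, yb, c("x", "y", "z"), k = 2, family = "logistic"))

  # oracle: refit every enumerated spec with the R engine, apply the same
  # all-significant-then-AIC rule
  specs <- enumerate_models(c("x", "y", "z"), k = 2, family = "logistic")
  fits <- lapply(specs, function(s)
    suppressWarnings(tryCatch(fit_glm(s, expr, yb), error = function(e) NULL)))
  keep <- !vapply(fits, is.null, logical(1)) &
    !vapply(fits, function(f) f$separation_flag, logical(1))
  allsig <- keep & vapply(fits, function(f) isTRUE(f$all_significant),
                          logical(1))
  pool <- if (any(allsig)) which(allsig) else which(keep)
  aics <- vapply(fits[pool], function(f) f$aic, numeric(1))
  best_oracle <- fits[pool][[which.min(aics)]]
  expect_setequal(got$best$spec$terms, best_oracle$spec$terms)
  expect_equal(got$best$aic, best_oracle$aic, tolerance = 1e-6)
  expect_equal(got$n_models, 3 * 7)
})

test_that("k = 1 search ranks a single strong main effect first", {
  set.seed(61)
  n <- 80
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1.5 + 2 * x1))
  expr <- toy_expr(rbind(x1, x2, x3), feature_ids = c("s", "n1", "n2"))
  got <- search_best(expr, y, c("s", "n1", "n2"), k = 1, family = "logistic")
  expect_identical(got$best$spec$predictors, "s")
})

test_that("pure-noise search warns when no all-significant model exists", {
  set.seed(71)
  n <- 30
  expr <- toy_expr(matrix(rnorm(3 * n), 3), feature_ids = c("a", "b", "c"))
  y <- rbinom(n, 1, 0.4)
  expect_warning(
    got <- search_best(expr, y, c("a", "b", "c"), k = 2,
                       family = "logistic"),
    "WITHOUT")
  expect_false(got$found_all_significant)
})

test_that("coefficient recovery: fitting the generating spec at large n", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 2000
    x1 <- rnorm(n); x2 <- rnorm(n)
    truth <- c(-0.5, 0.8, -0.6, 0.4)
    eta <- truth[1] + truth[2] * x1 + truth[3] * x2 + truth[4] * x1 * x2
    y <- rbinom(n, 1, plogis(eta))
    expr <- toy_expr(rbind(x1, x2), feature_ids = c("g1", "g2"))
    fit <- fit_glm(model_spec(c("g1", "g2"), c("g1", "g2", "g1:g2"),
                              family = "logistic"), expr, y)
    ok <- all(abs(coef(fit) - truth) <= 3 * fit$std_errors)
    hits <- hits + ok
  }
  expect_gte(hits, 4L)
})

test_that("linear family: squared predicted-vs-actual correlation equals R^2", {
  set.seed(81)
  n <- 30
  v <- matrix(rnorm(2 * n), 2)
  y <- 1 + v[1, ] - 0.5 * v[2, ] + rnorm(n)
  expr <- toy_expr(v, feature_ids = c("g1", "g2"))
  fit <- fit_glm(model_spec(c("g1", "g2"), family = "linear"), expr, y)
  r2_cor <- cor(fit$fitted, y)^2
  r2_def <- 1 - sum((y - fit$fitted)^2) / sum((y - mean(y))^2)
  expect_equal(r2_cor, r2_def, tolerance = 1e-10)
})

test_that("frozen reference models expose the printed constants and round-trip YAML", {
  m1 <- reference_model("eq1_pira")
  expect_equal(unname(coef(m1)["(Intercept)"]), -425.78)
  expect_equal(length(m1$spec$terms), 6)   # 2 mains + 4 interactions
  expect_equal(sum(grepl(":", m1$spec$terms)), 4)
  expect_equal(m1$threshold, 0.277)
  m2 <- reference_model("eq2_edss")
  expect_equal(unname(coef(m2)["hsa-miR-24-3p:hsa-miR-6090"]), 36.84)
  expect_equal(unname(coef(m2)["(Intercept)"]), 1183.40)
  expect_length(setdiff(m2$spec$predictors, m1$spec$predictors), 3)

  path <- tempfile(fileext = ".yaml")
  write_model_yaml(m1, path)
  back <- read_model_yaml(path)
  expect_equal(coef(back), coef(m1))
  expect_identical(back$spec$terms, m1$spec$terms)
  expect_equal(back$threshold, 0.277)
})

test_that("prediction evaluates the printed polynomial through the sigmoid", {
  m1 <- reference_model("eq1_pira")
  feats <- m1$spec$predictors
  zeros <- toy_expr(matrix(0, 4, 3), feature_ids = feats)
  expect_equal(unname(predict(m1, zeros, type = "link")),
               rep(-425.78, 3))
  expect_lt(unname(predict(m1, zeros, type = "response")[1]), 1e-30)
  expect_equal(unname(predict(m1, zeros, type = "class")), rep(0L, 3))

  set.seed(91)
  vals <- matrix(runif(4 * 50, 2, 12), 4, dimnames = list(feats, NULL))
  expr <- toy_expr(vals, feature_ids = feats)
  # independent direct evaluation of the printed polynomial + sigmoid
  z <- -425.78 + 43.66 * vals["hsa-miR-4485-5p", ] +
    154.79 * vals["hsa-miR-340-3p", ] -
    20.42 * vals["hsa-miR-6126", ] * vals["hsa-miR-4485-5p", ] +
    15.46 * vals["hsa-miR-223-3p", ] * vals["hsa-miR-6126", ] +
    15.59 * vals["hsa-miR-340-3p", ] * vals["hsa-miR-6126", ] -
    9.49 * vals["hsa-miR-340-3p", ] * vals["hsa-miR-223-3p", ]
  expect_equal(unname(predict(m1, expr, type = "link")), unname(z),
               tolerance = 1e-12)
  expect_equal(unname(predict(m1, expr, type = "response")),
               unname(1 / (1 + exp(-z))), tolerance = 1e-12)
  expect_equal(unname(predict(m1, expr, type = "class")),
               unname(as.integer(1 / (1 + exp(-z)) >= 0.277)))
  # a subject at Z = 0 scores 0.5 and is classified PIRA (0.5 >= 0.277)
  mz <- reference_model("eq1_pira")
  mz$coefficients["(Intercept)"] <- 0
  at_zero <- toy_expr(matrix(0, 4, 1), feature_ids = feats)
  expect_equal(unname(predict(mz, at_zero, type = "response")), 0.5)
  expect_equal(unname(predict(mz, at_zero, type = "class")), 1L)
  expect_error(predict(m1, toy_expr(matrix(1, 1, 2), feature_ids = "other")),
               "missing")
})
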