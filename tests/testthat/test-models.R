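test_that("standardization matches closed forms and stored recipes", {
  d <- data.frame(mean_nn_ms = c(1, 2, 3))
  out <- standardize_features(d)
  expect_equal(out$data$mean_nn_ms, c(-1, 0, 1))

  d2 <- data.frame(lf_hf_ratio = c(10, 100, 1000))
  out2 <- standardize_features(d2)
  expect_equal(out2$data$lf_hf_ratio, c(-1, 0, 1))
  expect_equal(out2$recipe$transform, "log10")

  # re-applying the stored recipe reproduces the table exactly
  redo <- standardize_features(d2, recipe = out2$recipe)
  expect_identical(redo$data, out2$data)

  d3 <- data.frame(lf_hf_ratio = c(-1, 2, 3))
  expect_error(standardize_features(d3), class = "neohrv_transform_error")
})

test_that("a saturated 2x2 logistic fit returns the log odds ratio", {
  a <- 30; b <- 10; c_ <- 12; d <- 25
  dat <- data.frame(
    x = c(rep(1, a + b), rep(0, c_ + d)),
    y = c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d)))
  m <- fit_hie_model(dat, "y", "x")
  expect_equal(m$terms$coefficient, log(a * d / (b * c_)), tolerance = 1e-8)
  expect_equal(m$n_used, a + b + c_ + d)
})

test_that("logistic fits recover known generating coefficients", {
  set.seed(31)
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- -0.5 + 1 * x1 - 0.7 * x2
  y <- rbinom(n, 1, plogis(eta))
  m <- fit_hie_model(data.frame(x1 = x1, x2 = x2, y = y), "y", c("x1", "x2"))
  td <- tidy(m)
  expect_true(all(abs(td$estimate - c(-0.5, 1, -0.7)) < 3 * td$std.error))
})

test_that("complete-case logic drops rows with any missing term", {
  set.seed(32)
  d <- data.frame(x = rnorm(60), y = rbinom(60, 1, 0.5))
  m0 <- fit_hie_model(d, "y", "x")
  extra <- rbind(d, data.frame(x = NA, y = 1))
  m1 <- fit_hie_model(extra, "y", "x")
  expect_equal(m1$terms$coefficient, m0$terms$coefficient)
  expect_equal(m1$n_dropped, 1)
})

test_that("perfect separation triggers a warning, constant outcome an error", {
  d <- data.frame(x = c(1, 2, 3, 11, 12, 13), y = c(0, 0, 0, 1, 1, 1))
  expect_warning(fit_hie_model(d, "y", "x"), class = "neohrv_separation")
  expect_error(fit_hie_model(data.frame(x = rnorm(10), y = rep(1, 10)),
                             "y", "x"),
               class = "neohrv_degenerate_outcome")
})

test_that("univariable screening reports definitional quantities", {
  set.seed(33)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x))
  d <- data.frame(x = x, x_copy = x, z = rnorm(n), y = y)
  scr <- univariable_screen(d, "y", c("x", "x_copy", "z"))
  expect_equal(scr$or, exp(scr$estimate))
  expect_true(all(scr$conf.low < scr$or & scr$or < scr$conf.high))
  # duplicated predictors: exactly one survives pruning
  dup <- scr[scr$variable %in% c("x", "x_copy"), ]
  expect_equal(sum(dup$kept), 1)
  expect_equal(sum(is.na(dup$pruned_by)), 1)
})

test_that("null predictors are rarely eligible at the screening threshold", {
  set.seed(34)
  eligible <- replicate(60, {
    d <- data.frame(x = rnorm(300), y = rbinom(300, 1, 0.5))
    univariable_screen(d, "y", "x")$eligible
  })
  # under the null, P(eligible) = 0.25; bound the rate generously
  expect_lt(mean(eligible), 0.45)
  expect_gt(mean(eligible), 0.08)
})

test_that("published models reproduce their printed worked examples", {
  hrv <- published_model("hrv")
  zero_row <- tibble::as_tibble(setNames(as.list(rep(0, 6)),
                                         hrv$terms$term))
  expect_equal(qlogis(predict_risk(hrv, zero_row)), 0.49, tolerance = 1e-10)

  comb <- published_model("combined")
  row <- tibble::tibble(mean_nn_ms = 0, hf_power_ms2 = 0, lf_hf_ratio = 0,
                        tinn_ms = 0, mse_complexity_index = 0,
                        mse_short_slope = 0, foetal_distress = 0,
                        ga_weeks = 40, emergency_delivery = 0, apgar5 = 5,
                        ventilation_10min = 1)
  expect_equal(qlogis(predict_risk(comb, row)),
               11.49 - 0.28 * 40 - 0.06 * 5 + 2.19, tolerance = 1e-10)

  expect_error(published_model("other"))
  expect_equal(published_model("clinical")$provenance, "transcribed")
})

test_that("predicted risk is the inverse logit and respects monotonicity", {
  m <- published_model("clinical")
  base <- tibble::tibble(foetal_distress = 0, ga_weeks = 38.84,
                         emergency_delivery = 0, apgar5 = 0,
                         ventilation_10min = 0)
  # eta = 9.71 - 0.25 * 38.84 = 0: probability one half
  expect_equal(predict_risk(m, base), 0.5, tolerance = 1e-10)
  probs <- vapply(c(0, 1), function(v) {
    base$ventilation_10min <- v
    predict_risk(m, base)
  }, numeric(1))
  expect_gt(probs[2], probs[1])
  expect_error(predict_risk(m, base[, -1]), class = "neohrv_missing_term")
})

test_that("fitted probabilities average to the outcome prevalence", {
  set.seed(35)
  d <- data.frame(x = rnorm(500))
  d$y <- rbinom(500, 1, plogis(0.5 + d$x))
  m <- fit_hie_model(d, "y", "x")
  probs <- predict_risk(m, d)
  expect_equal(mean(probs), mean(d$y), tolerance = 1e-8)
})

test_that("models round-trip through JSON serialization", {
  m <- published_model("combined")
  path <- withr::local_tempfile(fileext = ".json")
  write_hie_model(m, path)
  m2 <- read_hie_model(path)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$terms$coefficient, m$terms$coefficient)
  row <- tibble::tibble(mean_nn_ms = 0.3, hf_power_ms2 = -1, lf_hf_ratio = 0.2,
                        tinn_ms = 0, mse_complexity_index = 1,
                        mse_short_slope = -0.5, foetal_distress = 1,
                        ga_weeks = 39, emergency_delivery = 1, apgar5 = 3,
                        ventilation_10min = 1)
  expect_identical(predict_risk(m2, row), predict_risk(m, row))

  set.seed(36)
  d <- data.frame(x = rnorm(80))
  d$y <- rbinom(80, 1, plogis(d$x))
  fm <- fit_hie_model(d, "y", "x")
  path2 <- withr::local_tempfile(fileext = ".json")
  write_hie_model(fm, path2)
  expect_equal(predict_risk(read_hie_model(path2), d), predict_risk(fm, d),
               tolerance = 1e-12)
})
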