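test_that("time-domain features match closed forms", {
  td <- time_domain(c(400, 500, 600))
  expect_equal(td$mean_nn_ms, 500)
  expect_equal(td$sdnn_ms, 100)

  const <- time_domain(rep(500, 300))
  expect_equal(const$mean_nn_ms, 500)
  expect_equal(const$sdnn_ms, 0)
  expect_lte(const$tinn_ms, 7.8125 + 1e-9)

  expect_error(time_domain(500), class = "neohrv_insufficient_data")
})

test_that("TINN recovers the base width of a triangular histogram", {
  bin <- 7.8125
  edges <- seq(50 * bin, 76 * bin, by = bin)       # 390.6 to 593.8 ms
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  counts <- pmin(seq_along(centers) - 1, length(centers) - seq_along(centers))
  counts <- round(200 * pmax(counts, 0) / max(counts))
  x <- rep(centers, counts)
  td <- time_domain(x, tinn_bin_ms = bin)
  # candidate triangle feet lie on bin edges while the true zeros sit at
  # bin centers, so the fitted base can be off by up to one bin per side
  expect_lte(abs(td$tinn_ms - (76 - 50) * bin), 2 * bin)
})

test_that("a pure HF sinusoid integrates to its theoretical band power", {
  A <- 20
  t <- seq(0.5, 300, by = 0.5)
  iv <- 500 + A * sin(2 * pi * 0.5 * t)
  bp <- band_powers(t, iv)
  expect_equal(bp$hf_power_ms2, A^2 / 2, tolerance = 0.05 * A^2 / 2)
  expect_lt(bp$vlf_power_ms2 + bp$lf_power_ms2, 0.02 * bp$hf_power_ms2)
})

test_that("band powers sum to the tachogram variance for white noise", {
  set.seed(11)
  ok <- replicate(5, {
    t <- seq(0.25, 300, by = 0.25)
    iv <- 500 + rnorm(length(t), sd = 10)
    bp <- band_powers(t, iv)
    tot <- bp$vlf_power_ms2 + bp$lf_power_ms2 + bp$hf_power_ms2
    abs(tot - var(iv)) / var(iv) < 0.15
  })
  expect_true(all(ok))
})

test_that("swapping LF and HF content swaps the band outputs", {
  t <- seq(0.25, 300, by = 0.25)
  a <- 500 + 15 * sin(2 * pi * 0.1 * t) + 5 * sin(2 * pi * 0.5 * t)
  b <- 500 + 5 * sin(2 * pi * 0.1 * t) + 15 * sin(2 * pi * 0.5 * t)
  bpa <- band_powers(t, a)
  bpb <- band_powers(t, b)
  expect_equal(bpa$lf_power_ms2, bpb$hf_power_ms2, tolerance = 0.05)
  expect_equal(bpa$hf_power_ms2, bpb$lf_power_ms2, tolerance = 0.05)
})

test_that("band powers are invariant to a constant interval shift", {
  set.seed(3)
  t <- seq(0.25, 300, by = 0.25)
  iv <- 500 + 10 * sin(2 * pi * 0.3 * t) + rnorm(length(t), sd = 3)
  expect_equal(band_powers(t, iv), band_powers(t, iv + 100))
})

test_that("TINN, SDNN and band powers are invariant to time reversal", {
  set.seed(4)
  t <- seq(0.25, 300, by = 0.25)
  iv <- 520 + 12 * sin(2 * pi * 0.2 * t) + rnorm(length(t), sd = 5)
  fwd <- time_domain(iv)
  rev_ <- time_domain(rev(iv))
  expect_equal(fwd$sdnn_ms, rev_$sdnn_ms)
  expect_equal(fwd$tinn_ms, rev_$tinn_ms)
  expect_equal(band_powers(t, iv)$hf_power_ms2,
               band_powers(t, rev(iv))$hf_power_ms2, tolerance = 1e-6)
})

test_that("sample entropy handles regular and degenerate series", {
  expect_equal(sample_entropy(rep(5, 50)), 0)
  x <- rep(c(1, 2), 50)
  expect_equal(sample_entropy(x, m = 2, r = 0.2 * sd(x)), 0)
  expect_equal(sample_entropy(x, m = 2, r = 0.2 * sd(x)),
               sampen_oracle(x, 2, 0.2 * sd(x)))
  expect_error(sample_entropy(c(1, 2, 3), m = 2),
               class = "neohrv_insufficient_data")
})

test_that("sample entropy equals the brute-force template count oracle", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(20:120, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                round(runif(n, 0, 5)),            # heavy ties
                as.numeric(arima.sim(list(ar = 0.7), n)))
    r <- runif(1, 0.1, 0.3) * max(sd(x), 1e-3)
    expect_equal(sample_entropy(x, m = 2, r = r), sampen_oracle(x, 2, r),
                 tolerance = 1e-12)
  }
})

test_that("white-noise sample entropy sits near the iid Gaussian limit", {
  set.seed(5)
  x <- rnorm(5000)
  limit <- -log(2 * pnorm(0.15 / sqrt(2)) - 1)
  expect_equal(sample_entropy(x), limit, tolerance = 0.15)
})

test_that("the MSE curve starts at the raw-series entropy and is finite", {
  set.seed(6)
  x <- rnorm(500)
  curve <- mse_curve(x)
  expect_equal(curve$entropy[1], sample_entropy(x))
  expect_equal(curve$scale, 1:20)

  const <- mse_curve(rep(3, 200))
  expect_true(all(const$entropy == 0))

  expect_error(mse_curve(rnorm(30)), class = "neohrv_insufficient_data")
})

test_that("white-noise MSE decreases over the long scales", {
  set.seed(8)
  x <- rnorm(1500)
  curve <- mse_curve(x)
  long <- curve$entropy[curve$scale >= 10]
  expect_lt(slope_oracle(10:20, long), 0)
  expect_true(all(diff(long) < 0.05))   # near-monotone decline
})

test_that("MSE curve features match closed forms and the slope oracle", {
  flat <- tibble::tibble(scale = 1:20, entropy = rep(1.3, 20))
  f <- mse_features(flat)
  expect_equal(f$mse_complexity_index, 19 * 1.3)
  expect_equal(f$mse_max, 1.3)
  expect_equal(f$mse_short_slope, 0)
  expect_equal(f$mse_long_slope, 0)

  line <- tibble::tibble(scale = 1:20, entropy = as.numeric(1:20))
  fl <- mse_features(line)
  expect_equal(fl$mse_short_slope, 1)
  expect_equal(fl$mse_long_slope, 1)
  expect_equal(fl$mse_max, 20)
  expect_equal(fl$mse_complexity_index, (20^2 - 1) / 2)

  set.seed(9)
  rnd <- tibble::tibble(scale = 1:20, entropy = runif(20))
  fr <- mse_features(rnd)
  expect_equal(fr$mse_short_slope, slope_oracle(1:5, rnd$entropy[1:5]))
  expect_equal(fr$mse_long_slope, slope_oracle(6:20, rnd$entropy[6:20]))

  rnd$entropy[3] <- NA
  fna <- mse_features(rnd)
  expect_true(is.na(fna$mse_complexity_index))
  expect_true(is.na(fna$mse_short_slope))
  expect_false(is.na(fna$mse_long_slope))
})

test_that("a single-segment epoch reproduces that segment's features", {
  rr <- simulate_rr(group_profile(0, 500, lf_amp_ms = 10, hf_amp_ms = 3,
                                  noise_sd_ms = 5, artifact_rate = 0),
                    duration_s = 600, seed = 10)
  seg <- segment_epoch(rr, epoch_duration_s = 600, segment_s = 600,
                       step_s = 600)
  f <- hrv_features(rr, segments = seg)
  expect_equal(f$n_segments, 1)
  inside <- rr$time_s > seg$start_s[1] & rr$time_s <= seg$end_s[1]
  expect_equal(f$mean_nn_ms, mean(rr$interval_ms[inside]))
  expect_equal(f$sdnn_ms, sd(rr$interval_ms[inside]))
  curve <- mse_curve(rr$interval_ms[inside], mse_config())
  expect_equal(f$mse_max, mse_features(curve)$mse_max)
})

test_that("feature extraction is deterministic and excludes flagged time", {
  rr <- simulate_rr(default_group_profiles()$mild, duration_s = 900,
                    seed = 12)
  rr <- flag_artifacts(rr)
  f1 <- hrv_features(rr, mse = NULL)
  f2 <- hrv_features(rr, mse = NULL)
  expect_equal(f1, f2)
  expect_equal(f1$removed_fraction,
               sum(rr$interval_ms[rr$artifact]) / sum(rr$interval_ms))
})
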