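test_that("a noiseless profile yields a constant series covering the epoch", {
  rr <- simulate_rr(quiet_profile(500), duration_s = 600, seed = 1)
  expect_equal(nrow(rr), 1200)
  expect_true(all(rr$interval_ms == 500))
  expect_false(any(rr$artifact))
  expect_gte(max(rr$time_s), 600)
  # ground-truth recovery of the mean NN level
  expect_lt(abs(mean(rr$interval_ms) - 500), 0.5)
})

test_that("invalid generating specifications are rejected", {
  expect_error(simulate_rr(quiet_profile(), duration_s = 100),
               class = "neohrv_invalid_spec")
  expect_error(group_profile(0, mean_nn_ms = -5),
               class = "neohrv_invalid_spec")
  expect_error(group_profile(0, 500, artifact_rate = 0.6),
               class = "neohrv_invalid_spec")
  expect_error(group_profile(0, 500, lf_freq_hz = 1, hf_freq_hz = 0.5),
               class = "neohrv_invalid_spec")
  expect_error(clinical_profile(2, 1, 5, 2, ventilation_prob = 1.4,
                                emergency_delivery_prob = 0.5,
                                foetal_distress_prob = 0.5),
               class = "neohrv_invalid_spec")
  expect_error(cohort_spec(0), class = "neohrv_invalid_spec")
  expect_error(cohort_spec(5, epoch_duration_s = 300),
               class = "neohrv_invalid_spec")
})

test_that("identical seeds reproduce identical cohorts", {
  spec <- cohort_spec(n_per_group = 2, epoch_duration_s = 600, seed = 42)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(cohort_spec(2, epoch_duration_s = 600, seed = 43))
  expect_false(identical(c1$rr[[1]]$interval_ms, c3$rr[[1]]$interval_ms))
})

test_that("HF band power increases monotonically with the HF amplitude", {
  powers <- vapply(c(2, 4, 6, 8, 10), function(a) {
    p <- group_profile(0, 500, lf_amp_ms = 0, hf_amp_ms = a,
                       noise_sd_ms = 0, artifact_rate = 0)
    rr <- simulate_rr(p, duration_s = 600, seed = 3)
    band_powers(rr$time_s, rr$interval_ms)$hf_power_ms2
  }, numeric(1))
  expect_true(all(diff(powers) > 0))
})

test_that("an HF-only profile puts its power in the HF band", {
  p <- group_profile(0, 500, lf_amp_ms = 0, hf_amp_ms = 10,
                     noise_sd_ms = 0, artifact_rate = 0)
  rr <- simulate_rr(p, duration_s = 600, seed = 4)
  bp <- band_powers(rr$time_s, rr$interval_ms)
  expect_gt(bp$hf_power_ms2, 10 * bp$lf_power_ms2)
})

test_that("injected artifacts are halved or doubled beats flagged in truth", {
  p <- group_profile(0, 500, lf_amp_ms = 0, hf_amp_ms = 0, noise_sd_ms = 0,
                     artifact_rate = 0.05)
  rr <- simulate_rr(p, duration_s = 1200, seed = 9)
  frac <- mean(rr$artifact)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
  bad <- rr$interval_ms[rr$artifact]
  expect_true(all(abs(bad - 250) < 1e-9 | abs(bad - 1000) < 1e-9))
  expect_true(all(rr$interval_ms[!rr$artifact] == 500))
})

test_that("clinical generation respects sizes, missingness and contrasts", {
  profiles <- default_clinical_profiles()
  none <- lapply(profiles, function(p) { p$missingness <- numeric(0); p })
  tiny <- simulate_clinical(none, n_per_group = 1, seed = 1)
  expect_equal(nrow(tiny), 2)
  expect_false(anyNA(tiny))
  expect_equal(tiny$group, c(0L, 1L))

  all_gone <- lapply(profiles, function(p) {
    p$missingness <- c(lactate = 1); p
  })
  gone <- simulate_clinical(all_gone, n_per_group = 10, seed = 2)
  expect_true(all(is.na(gone$lactate)))

  big <- simulate_clinical(profiles, n_per_group = 400, seed = 5)
  by_grp <- split(big, big$group)
  vent <- vapply(by_grp, function(d) mean(d$ventilation_10min, na.rm = TRUE),
                 numeric(1))
  expect_gt(vent[["1"]], vent[["0"]])
  apgar5 <- vapply(by_grp, function(d) median(d$apgar5, na.rm = TRUE),
                   numeric(1))
  expect_lt(apgar5[["1"]], apgar5[["0"]])
  expect_true(all(big$apgar1 >= 0 & big$apgar1 <= 10, na.rm = TRUE))
})

test_that("identical group profiles produce no spurious univariable contrast", {
  # null-contrast calibration: with the same generating profile for both
  # groups, the univariable Wald test should reject at its nominal rate
  p <- default_group_profiles()$mild
  n_rep <- 60
  set.seed(2718)
  hits <- matrix(FALSE, n_rep, 2,
                 dimnames = list(NULL, c("mean_nn_ms", "lf_hf_ratio")))
  for (rep in seq_len(n_rep)) {
    spec <- cohort_spec(20, group_profiles = list(mild = p, severe = p),
                        epoch_duration_s = 600,
                        seed = sample.int(1e6, 1))
    cohort <- simulate_cohort(spec)
    feats <- extract_features(cohort, mse = NULL)
    std <- standardize_features(feats, cols = colnames(hits))$data
    scr <- univariable_screen(std, "group", colnames(hits))
    hits[rep, ] <- scr$p.value[match(colnames(hits), scr$variable)] < 0.05
  }
  # binomial upper bound for a 5% rate over n_rep replicates
  upper <- qbinom(0.999, n_rep, 0.05)
  expect_lte(sum(hits[, "mean_nn_ms"]), upper)
  expect_lte(sum(hits[, "lf_hf_ratio"]), upper)
})
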