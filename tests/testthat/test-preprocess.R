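test_that("R peaks of a clean impulse train are recovered at known spacing", {
  fx <- make_ecg(n_beats = 120, interval_s = 0.5, fs = 250)
  rr <- detect_rpeaks(fx$ecg, fx$fs)
  expect_gte(nrow(rr), 115)
  # one-sample tolerance at 250 Hz is 4 ms
  expect_true(all(abs(rr$interval_ms - 500) <= 4 + 1e-9))
  expect_false(any(rr$artifact))
})

test_that("R-peak detection survives additive noise at 10% peak amplitude", {
  set.seed(7)
  fx <- make_ecg(n_beats = 200, interval_s = 0.5, fs = 250, noise_sd = 0.1)
  rr <- detect_rpeaks(fx$ecg, fx$fs)
  beat_times <- c(rr$time_s[1] - rr$interval_ms[1] / 1000, rr$time_s)
  hits <- vapply(fx$peaks_s, function(t) any(abs(beat_times - t) < 0.03),
                 logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("degenerate ECG inputs raise the documented errors", {
  expect_error(detect_rpeaks(numeric(0), 250),
               class = "neohrv_insufficient_data")
  expect_error(detect_rpeaks(rep(0.5, 2500), 250),
               class = "neohrv_no_peaks")
  expect_error(detect_rpeaks(rnorm(2500), 50),
               class = "neohrv_invalid_spec")
})

test_that("artifact rules flag range and median-deviation violations only", {
  rr <- constant_rr(500, 600)
  expect_false(any(flag_artifacts(rr)$artifact))

  rr2 <- rr
  rr2$interval_ms[100] <- 1500   # out of range and >30% off the median
  flagged <- flag_artifacts(rr2)
  expect_identical(which(flagged$artifact), 100L)
  # intervals must never be modified
  expect_identical(flagged$interval_ms, rr2$interval_ms)

  expect_error(flag_artifacts(constant_rr(500, 600)[1:5, ]),
               class = "neohrv_insufficient_data")
})

test_that("rule-based flags recover injected artifacts with few false alarms", {
  p <- group_profile(0, 550, lf_amp_ms = 20, hf_amp_ms = 3,
                     noise_sd_ms = 10, noise_ar1 = 0.5,
                     artifact_rate = 0.02)
  truth_hits <- 0; truth_n <- 0; fp <- 0; clean_n <- 0
  for (seed in 1:5) {
    rr <- simulate_rr(p, duration_s = 1200, seed = seed)
    truth <- rr$artifact
    flag <- flag_artifacts(rr)$artifact
    truth_hits <- truth_hits + sum(flag & truth)
    truth_n <- truth_n + sum(truth)
    fp <- fp + sum(flag & !truth)
    clean_n <- clean_n + sum(!truth)
  }
  expect_gte(truth_hits / truth_n, 0.9)
  expect_lte(fp / clean_n, 0.02)
})

test_that("a clean one-hour epoch tiles into 23 overlapping segments", {
  rr <- simulate_rr(quiet_profile(500), duration_s = 3600, seed = 1)
  seg <- segment_epoch(rr, epoch_duration_s = 3600)
  expect_equal(nrow(seg), 23)
  expect_equal(seg$start_s, seq(0, 3300, by = 150))
  expect_true(all(seg$end_s - seg$start_s == 300))
  expect_true(all(seg$retained))
  expect_equal(attr(seg, "removed_fraction"), 0)
})

test_that("segments exceeding the artifact-time budget are dropped", {
  rr <- constant_rr(500, 3600)
  rr$artifact[rr$time_s <= 300] <- TRUE
  seg <- segment_epoch(rr, epoch_duration_s = 3600)
  expect_false(seg$retained[1])           # fully flagged
  # second segment (150-450 s) carries exactly 50% flagged time: retained
  expect_equal(seg$artifact_frac[2], 0.5, tolerance = 0.01)
  expect_true(seg$retained[2])

  rr2 <- constant_rr(500, 3600)
  rr2$artifact[rr2$time_s <= 340] <- TRUE # second segment now > 50%
  seg2 <- segment_epoch(rr2, epoch_duration_s = 3600)
  expect_false(seg2$retained[2])
  expect_true(seg2$retained[3])

  # flagging can only remove segments, never add them
  expect_lte(sum(seg$retained), sum(segment_epoch(constant_rr(500, 3600),
                                                  3600)$retained))
  expect_gte(attr(seg, "removed_fraction"), 0)
  expect_lte(attr(seg, "removed_fraction"), 1)
})

test_that("short epochs are rejected", {
  rr <- constant_rr(500, 600)
  short <- rr[rr$time_s < 299, ]
  class(short) <- class(rr)
  expect_error(segment_epoch(short), class = "neohrv_insufficient_data")
})

test_that("segmentation is equivariant under time translation", {
  rr <- simulate_rr(quiet_profile(480), duration_s = 1200, seed = 2)
  shifted <- rr
  shifted$time_s <- shifted$time_s + 150
  s1 <- segment_epoch(rr, epoch_duration_s = 1200)
  s2 <- segment_epoch(shifted, epoch_duration_s = 1200)
  expect_equal(s2$start_s, s1$start_s + 150)
  expect_equal(s2$n_beats, s1$n_beats)
})

test_that("the earliest admissible one-hour window is selected", {
  rr <- simulate_rr(quiet_profile(500), duration_s = 3 * 3600, seed = 3,
                    start_age_h = 4.4)
  ep <- select_earliest_epoch(rr)
  expect_equal(attr(ep, "start_age_h"), 4.4)
  expect_equal(diff(range(ep$time_s)), 3600, tolerance = 1)

  late <- simulate_rr(quiet_profile(500), duration_s = 7200, seed = 4,
                      start_age_h = 11.9)
  expect_error(select_earliest_epoch(late), class = "neohrv_no_epoch")

  short <- simulate_rr(quiet_profile(500), duration_s = 1800, seed = 5,
                       start_age_h = 1)
  expect_error(select_earliest_epoch(short), class = "neohrv_no_epoch")
})

test_that("a usability requirement shifts the window past flagged stretches", {
  rr <- constant_rr(500, 2 * 3600, start_age_h = 2)
  rr$artifact[rr$time_s <= 2400] <- TRUE  # first 40 min unusable
  ep <- select_earliest_epoch(rr, min_usable_frac = 0.5)
  start_off <- (attr(ep, "start_age_h") - 2) * 3600
  # flagged time in a window starting at s is 2400 - s, so the earliest
  # admissible start (<= 50% flagged) is s = 600
  expect_gte(start_off, 600 - 1e-6)
  expect_lte(start_off, 630)    # earliest admissible 30-s grid point
})
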