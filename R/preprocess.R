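#' Detect R peaks in a single-lead ECG
#'
#' A Pan-Tompkins-style detector: the signal is band-pass filtered to the
#' QRS band (5-30 Hz, zero-phase Butterworth), squared, smoothed with a
#' short moving-average energy window, and local energy maxima above an
#' adaptive per-block threshold are kept, subject to a physiologic
#' refractory period. Peak locations are refined to the largest absolute
#' filtered amplitude near each energy maximum.
#'
#' @param ecg Numeric vector of ECG samples (a single channel).
#' @param fs_hz Sampling rate in Hz (at least 100).
#' @param start_age_h Postnatal age (hours) at the first sample.
#' @param refractory_s Minimum separation between detected peaks, s.
#' @param threshold_frac Adaptive threshold as a fraction of the rolling
#'   block energy maximum.
#'
#' @return An `rr_series` tibble (see [simulate_rr()]) with one row per
#'   detected beat after the first, an all-`FALSE` artifact mask, and the
#'   interval preceding each beat in `interval_ms`.
#' @export
detect_rpeaks <- function(ecg, fs_hz, start_age_h = 0,
                          refractory_s = 0.2, threshold_frac = 0.25) {
  if (!is.numeric(ecg) || length(ecg) < 2 * fs_hz) {
    abort("`ecg` must contain at least two seconds of samples.",
          class = "neohrv_insufficient_data")
  }
  if (fs_hz < 100) {
    abort("`fs_hz` must be at least 100 Hz.", class = "neohrv_invalid_spec")
  }
  bp <- signal::butter(2, c(5, 30) / (fs_hz / 2), type = "pass")
  filt <- signal::filtfilt(bp, ecg - mean(ecg))
  energy <- filt^2
  win <- max(3L, round(0.08 * fs_hz))
  energy <- as.numeric(stats::filter(energy, rep(1 / win, win), sides = 2))
  energy[is.na(energy)] <- 0
  if (max(energy) <= 0 || sd(filt) < 1e-12) {
    abort("No R peaks found: the record appears to be flat.",
          class = "neohrv_no_peaks")
  }
  # adaptive threshold: fraction of the energy maximum in 10-s blocks,
  # floored at a fraction of the global median block maximum so silent
  # blocks do not admit noise
  block <- pmin(ceiling(seq_along(energy) / (10 * fs_hz)),
                ceiling(length(energy) / (10 * fs_hz)))
  block_max <- tapply(energy, block, max)
  thr <- threshold_frac * as.numeric(block_max)[block]
  thr <- pmax(thr, threshold_frac * 0.2 * median(block_max))
  is_peak <- c(FALSE, diff(sign(diff(energy))) < 0, FALSE) & energy > thr
  cand <- which(is_peak)
  if (!length(cand)) {
    abort("No R peaks found above threshold.", class = "neohrv_no_peaks")
  }
  # refractory: greedy keep-largest within refractory_s
  keep <- logical(length(cand))
  ord <- order(energy[cand], decreasing = TRUE)
  taken <- rep(FALSE, length(ecg))
  ref <- round(refractory_s * fs_hz)
  for (k in ord) {
    i <- cand[k]
    if (!taken[i]) {
      keep[k] <- TRUE
      lo <- max(1, i - ref); hi <- min(length(ecg), i + ref)
      taken[lo:hi] <- TRUE
    }
  }
  peaks <- sort(cand[keep])
  # refine to the local absolute maximum of the filtered signal
  half <- round(0.05 * fs_hz)
  peaks <- vapply(peaks, function(i) {
    lo <- max(1L, as.integer(i - half))
    hi <- min(length(filt), as.integer(i + half))
    lo + which.max(abs(filt[lo:hi])) - 1L
  }, integer(1))
  peaks <- unique(peaks)
  if (length(peaks) < 2) {
    abort("Fewer than two R peaks found.", class = "neohrv_no_peaks")
  }
  times <- peaks / fs_hz
  new_rr_series(times[-1], diff(times) * 1000,
                start_age_h = start_age_h)
}

#' Flag artifactual beats in an RR series
#'
#' Automated stand-in for manual artifact annotation: a beat is flagged
#' when its interval is outside a physiologic range gate or deviates from
#' the running median of the surrounding beats by more than a relative
#' threshold. Intervals are never modified, only flagged; downstream
#' feature extraction excludes flagged beats.
#'
#' @param rr An `rr_series` tibble.
#' @param min_ms,max_ms Physiologic range gate (ms).
#' @param rel_dev Maximum allowed relative deviation from the running
#'   median (default 0.3, i.e. 30%).
#' @param window Running-median window in beats (odd; default 11).
#'
#' @return The input with its `artifact` column replaced by the rule-based
#'   flags.
#' @export
flag_artifacts <- function(rr, min_ms = 200, max_ms = 1200,
                           rel_dev = 0.3, window = 11) {
  check_rr(rr)
  if (nrow(rr) < 10) {
    abort("At least 10 beats are required.",
          class = "neohrv_insufficient_data")
  }
  x <- rr$interval_ms
  med <- stats::runmed(x, k = window, endrule = "median")
  flag <- x < min_ms | x > max_ms | abs(x - med) > rel_dev * med
  rr$artifact <- as.logical(flag)
  rr
}

check_rr <- function(rr) {
  if (!is.data.frame(rr) ||
      !all(c("time_s", "interval_ms", "artifact") %in% names(rr))) {
    abort("Expected an `rr_series` with columns time_s, interval_ms, artifact.",
          class = "neohrv_invalid_spec")
  }
  invisible(rr)
}

rr_epoch_start <- function(rr) rr$time_s[1] - rr$interval_ms[1] / 1000

#' Tile an epoch into overlapping five-minute segments
#'
#' Segments of `segment_s` seconds are tiled from the epoch start at
#' `step_s` steps (default 300 s with 150 s steps, i.e. 50% overlap).
#' A segment is dropped when more than `max_artifact_frac` of its covered
#' time belongs to flagged beats; artifact weight is measured in time, not
#' beat count, so missed-beat artifacts weigh correctly. A clean one-hour
#' epoch yields 23 segments.
#'
#' @param rr An `rr_series` tibble (run [flag_artifacts()] first).
#' @param epoch_duration_s Epoch duration; when `NULL`, the time span of
#'   the series is used.
#' @param segment_s,step_s Segment length and tiling step, s.
#' @param max_artifact_frac Maximum tolerated artifact time fraction.
#'
#' @return A tibble of class `segment_set` with one row per tiled segment
#'   (`segment`, `start_s`, `end_s`, `n_beats`, `artifact_frac`,
#'   `retained`) and attribute `removed_fraction`, the fraction of the
#'   epoch's covered time belonging to flagged beats.
#' @export
segment_epoch <- function(rr, epoch_duration_s = NULL,
                          segment_s = 300, step_s = 150,
                          max_artifact_frac = 0.5) {
  check_rr(rr)
  t0 <- rr_epoch_start(rr)
  span <- max(rr$time_s) - t0
  dur <- epoch_duration_s %||% span
  if (dur < segment_s || span < segment_s) {
    abort(sprintf("Epoch of %.0f s is shorter than one %d s segment.",
                  min(dur, span), segment_s),
          class = "neohrv_insufficient_data")
  }
  starts <- seq(0, dur - segment_s, by = step_s)
  iv_s <- rr$interval_ms / 1000
  seg <- purrr::map_dfr(seq_along(starts), function(k) {
    lo <- t0 + starts[k]; hi <- lo + segment_s
    idx <- which(rr$time_s > lo & rr$time_s <= hi)
    covered <- sum(iv_s[idx])
    art <- if (length(idx)) sum(iv_s[idx][rr$artifact[idx]]) / covered else 1
    tibble::tibble(segment = k, start_s = lo, end_s = hi,
                   n_beats = length(idx), artifact_frac = art)
  })
  seg$retained <- seg$artifact_frac <= max_artifact_frac & seg$n_beats >= 2
  removed <- sum(iv_s[rr$artifact]) / sum(iv_s)
  attr(seg, "removed_fraction") <- removed
  class(seg) <- c("segment_set", class(seg))
  seg
}

#' Extract the earliest admissible one-hour epoch from a record
#'
#' Returns the earliest contiguous window of `duration_s` seconds that
#' lies within the record, ends before `max_age_h` hours of postnatal
#' age and, when `min_usable_frac` is set, has at least that fraction of
#' its covered time in unflagged beats. Candidate window starts advance
#' from the record start in `step_s` steps.
#'
#' @param rr An `rr_series` tibble whose `start_age_h` attribute gives the
#'   postnatal age at the record start.
#' @param max_age_h Latest allowed postnatal age (hours) for the epoch
#'   end (default 12).
#' @param duration_s Epoch duration, s (default 3600).
#' @param min_usable_frac Optional minimum fraction of unflagged covered
#'   time required for a window to be admissible.
#' @param step_s Search step for candidate window starts, s.
#'
#' @return An `rr_series` tibble restricted to the selected window, with
#'   `start_age_h` updated to the window start.
#' @export
select_earliest_epoch <- function(rr, max_age_h = 12, duration_s = 3600,
                                  min_usable_frac = NULL, step_s = 30) {
  check_rr(rr)
  age0 <- attr(rr, "start_age_h") %||% 0
  t0 <- rr_epoch_start(rr)
  span <- max(rr$time_s) - t0
  latest_start <- min(span - duration_s, max_age_h * 3600 - age0 * 3600 - duration_s)
  if (latest_start < 0) {
    abort(sprintf(
      "No %.0f s epoch fits before %.1f h of age in this record.",
      duration_s, max_age_h), class = "neohrv_no_epoch")
  }
  iv_s <- rr$interval_ms / 1000
  for (start in seq(0, latest_start, by = step_s)) {
    lo <- t0 + start; hi <- lo + duration_s
    idx <- which(rr$time_s > lo & rr$time_s <= hi)
    if (!length(idx)) next
    ok <- if (is.null(min_usable_frac)) TRUE else {
      usable <- sum(iv_s[idx][!rr$artifact[idx]]) / sum(iv_s[idx])
      usable >= min_usable_frac
    }
    if (ok) {
      out <- rr[idx, ]
      attr(out, "start_age_h") <- age0 + start / 3600
      class(out) <- c("rr_series", setdiff(class(out), "rr_series"))
      return(out)
    }
  }
  abort("No admissible epoch found under the usability requirement.",
        class = "neohrv_no_epoch")
}
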