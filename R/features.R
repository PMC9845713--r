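#' Time-domain HRV features of one segment
#'
#' Mean NN interval, sample standard deviation (SDNN), and TINN, the base
#' width of the best least-squares triangular fit to the NN-interval
#' histogram at the conventional 1/128 s (7.8125 ms) bin width.
#'
#' @param intervals_ms Unflagged NN intervals (ms) of one segment; at
#'   least two are required.
#' @param tinn_bin_ms Histogram bin width for TINN, ms.
#'
#' @return A one-row tibble with `mean_nn_ms`, `sdnn_ms` and `tinn_ms`.
#' @export
time_domain <- function(intervals_ms, tinn_bin_ms = 7.8125) {
  if (length(intervals_ms) < 2) {
    abort("At least 2 intervals are required.",
          class = "neohrv_insufficient_data")
  }
  tibble::tibble(mean_nn_ms = mean(intervals_ms),
                 sdnn_ms = sd(intervals_ms),
                 tinn_ms = tinn(intervals_ms, tinn_bin_ms))
}

# TINN: histogram D over fixed-width bins; the fitted function is zero
# outside [N, M], rises linearly from (N, 0) to the histogram mode and
# falls to (M, 0). N and M range over bin edges below/above the mode and
# the squared-error-minimising pair gives TINN = M - N.
tinn <- function(x, bin_ms = 7.8125) {
  lo <- floor(min(x) / bin_ms) * bin_ms
  hi <- ceiling(max(x) / bin_ms) * bin_ms
  if (hi <= lo) hi <- lo + bin_ms
  edges <- seq(lo, hi, by = bin_ms)
  if (length(edges) < 2) edges <- c(lo, lo + bin_ms)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  mode_i <- which.max(counts)
  peak_t <- centers[mode_i]
  peak_h <- counts[mode_i]
  n_cand <- edges[edges <= peak_t]
  m_cand <- edges[edges >= peak_t]
  best <- Inf; best_width <- bin_ms
  for (N in n_cand) {
    for (M in m_cand) {
      q <- numeric(length(centers))
      up <- centers >= N & centers <= peak_t
      dn <- centers > peak_t & centers <= M
      if (peak_t > N) q[up] <- peak_h * (centers[up] - N) / (peak_t - N)
      else q[centers == peak_t] <- peak_h
      if (M > peak_t) q[dn] <- peak_h * (M - centers[dn]) / (M - peak_t)
      err <- sum((counts - q)^2)
      if (err < best - 1e-12) { best <- err; best_width <- M - N }
    }
  }
  best_width
}

#' Per-epoch HRV feature set
#'
#' Computes, for each retained five-minute segment, the time-domain
#' features ([time_domain()]), spectral band powers ([band_powers()]) and
#' multiscale-entropy features ([mse_curve()] + [mse_features()]) on the
#' unflagged beats, then summarises each feature as the median over
#' segments (segment-level missing values ignored). The LF/HF ratio is
#' the median of the per-segment ratios, not the ratio of medians.
#'
#' @param rr An `rr_series` tibble for one epoch.
#' @param segments Optional [segment_epoch()] result; computed with
#'   defaults when `NULL`.
#' @param bands A [spectral_bands()] object.
#' @param mse An [mse_config()], or `NULL` to skip the entropy features.
#' @param tinn_bin_ms TINN histogram bin width, ms.
#'
#' @return A one-row tibble with the 11 feature columns `mean_nn_ms`,
#'   `sdnn_ms`, `tinn_ms`, `vlf_power_ms2`, `lf_power_ms2`,
#'   `hf_power_ms2`, `lf_hf_ratio`, `mse_complexity_index`, `mse_max`,
#'   `mse_short_slope`, `mse_long_slope`, plus `removed_fraction` and
#'   `n_segments`.
#' @export
hrv_features <- function(rr, segments = NULL, bands = spectral_bands(),
                         mse = mse_config(), tinn_bin_ms = 7.8125) {
  check_rr(rr)
  segments <- segments %||% segment_epoch(rr)
  kept <- segments[segments$retained, ]
  if (nrow(kept) == 0) {
    abort("No retained segments.", class = "neohrv_insufficient_data")
  }
  per_seg <- purrr::map_dfr(seq_len(nrow(kept)), function(k) {
    idx <- rr$time_s > kept$start_s[k] & rr$time_s <= kept$end_s[k] &
      !rr$artifact
    seg <- rr[idx, ]
    td <- time_domain(seg$interval_ms, tinn_bin_ms)
    sp <- tryCatch(band_powers(seg$time_s, seg$interval_ms, bands),
                   neohrv_insufficient_data = function(e) {
                     tibble::tibble(vlf_power_ms2 = NA_real_,
                                    lf_power_ms2 = NA_real_,
                                    hf_power_ms2 = NA_real_,
                                    lf_hf_ratio = NA_real_)
                   })
    ms <- if (is.null(mse)) {
      tibble::tibble(mse_complexity_index = NA_real_, mse_max = NA_real_,
                     mse_short_slope = NA_real_, mse_long_slope = NA_real_)
    } else {
      tryCatch(
        mse_features(mse_curve(seg$interval_ms, mse),
                     short_scales = mse$short_scales,
                     long_scales = mse$long_scales),
        neohrv_insufficient_data = function(e) {
          tibble::tibble(mse_complexity_index = NA_real_, mse_max = NA_real_,
                         mse_short_slope = NA_real_,
                         mse_long_slope = NA_real_)
        })
    }
    dplyr::bind_cols(td, sp, ms)
  })
  out <- dplyr::summarise(per_seg,
                          dplyr::across(dplyr::everything(),
                                        ~ median(.x, na.rm = TRUE)))
  out$removed_fraction <- attr(segments, "removed_fraction")
  out$n_segments <- nrow(kept)
  out
}

#' Extract HRV features for every subject of a cohort
#'
#' Applies the automated artifact rules, segmentation and
#' [hrv_features()] to each subject's RR epoch and binds the results to
#' the subject identifiers.
#'
#' @param cohort A tibble with `subject_id`, `group` and an `rr`
#'   list-column, as from [simulate_cohort()].
#' @param bands,mse,tinn_bin_ms Passed to [hrv_features()].
#' @param flag Apply [flag_artifacts()] before segmentation (default
#'   `TRUE`; set to `FALSE` when the mask is already final).
#' @param ... Passed to [flag_artifacts()].
#'
#' @return A tibble with `subject_id`, `group` and the [hrv_features()]
#'   columns, one row per subject.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_per_group = 2,
#'                                       epoch_duration_s = 600, seed = 3))
#' extract_features(cohort, mse = NULL)
extract_features <- function(cohort, bands = spectral_bands(),
                             mse = mse_config(), tinn_bin_ms = 7.8125,
                             flag = TRUE, ...) {
  stopifnot(all(c("subject_id", "rr") %in% names(cohort)))
  feats <- purrr::map_dfr(cohort$rr, function(rr) {
    if (flag) rr <- flag_artifacts(rr, ...)
    hrv_features(rr, bands = bands, mse = mse, tinn_bin_ms = tinn_bin_ms)
  })
  dplyr::bind_cols(
    cohort[, intersect(c("subject_id", "group"), names(cohort))],
    feats
  )
}

#' Names of the HRV feature columns
#'
#' @return Character vector of the 11 feature column names in table
#'   order.
#' @export
hrv_feature_names <- function() {
  c("mean_nn_ms", "sdnn_ms", "tinn_ms", "vlf_power_ms2", "lf_power_ms2",
    "hf_power_ms2", "lf_hf_ratio", "mse_complexity_index", "mse_max",
    "mse_short_slope", "mse_long_slope")
}

#' HRV features that are log10-transformed before standardization
#'
#' The positively skewed features (SDNN, the three band powers, the LF/HF
#' ratio and TINN) are log10-transformed before z-scoring; mean NN and
#' the entropy features (which can be negative) are standardized
#' directly.
#'
#' @return Character vector of feature column names.
#' @export
hrv_log10_features <- function() {
  c("sdnn_ms", "tinn_ms", "vlf_power_ms2", "lf_power_ms2", "hf_power_ms2",
    "lf_hf_ratio")
}
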