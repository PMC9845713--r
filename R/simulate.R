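#' Simulate a one-hour RR-interval epoch
#'
#' Generates a beat-interval series directly in interval space: each
#' interval is the profile's mean NN plus LF and HF sinusoidal modulation
#' (evaluated at the elapsed time of the preceding beat, with random
#' phases) plus AR(1) noise, clipped to the physiologic neonatal range of
#' 200-2000 ms. Beats are accumulated until the epoch duration is
#' covered. With a positive `artifact_rate`, randomly chosen beats are
#' corrupted into ectopic (halved interval) or missed (doubled interval)
#' detections and flagged in the ground-truth `artifact` column.
#'
#' @param profile A [group_profile()].
#' @param duration_s Epoch duration in seconds (at least 600).
#' @param seed Optional integer seed; when given the series is
#'   reproducible and the caller's RNG state is untouched.
#' @param start_age_h Postnatal age (hours) at the start of the epoch,
#'   stored as an attribute.
#'
#' @return A tibble of class `rr_series` with columns `time_s`
#'   (cumulative beat time from epoch start), `interval_ms` and
#'   `artifact` (ground-truth corruption flag), and attribute
#'   `start_age_h`.
#' @export
#' @examples
#' rr <- simulate_rr(default_group_profiles()$mild, duration_s = 600, seed = 1)
#' head(rr)
simulate_rr <- function(profile, duration_s = 3600, seed = NULL,
                        start_age_h = 4) {
  if (!inherits(profile, "group_profile")) {
    abort("`profile` must be a `group_profile`.", class = "neohrv_invalid_spec")
  }
  if (!is.numeric(duration_s) || duration_s < 600) {
    abort("`duration_s` must be at least 600 s.",
          class = "neohrv_invalid_spec")
  }
  with_seed_if(seed, {
    n_max <- ceiling(1.5 * duration_s * 1000 / profile$mean_nn_ms) + 10L
    phi1 <- runif(1, 0, 2 * pi)
    phi2 <- runif(1, 0, 2 * pi)
    rho <- profile$noise_ar1
    noise <- if (profile$noise_sd_ms > 0) {
      innov <- rnorm(n_max, sd = profile$noise_sd_ms * sqrt(1 - rho^2))
      as.numeric(stats::filter(innov, rho, method = "recursive"))
    } else {
      numeric(n_max)
    }
    intervals <- numeric(n_max)
    t_cur <- 0
    n <- 0L
    for (i in seq_len(n_max)) {
      iv <- profile$mean_nn_ms +
        profile$lf_amp_ms * sin(2 * pi * profile$lf_freq_hz * t_cur + phi1) +
        profile$hf_amp_ms * sin(2 * pi * profile$hf_freq_hz * t_cur + phi2) +
        noise[i]
      iv <- min(max(iv, 200), 2000)
      intervals[i] <- iv
      t_cur <- t_cur + iv / 1000
      n <- i
      if (t_cur >= duration_s) break
    }
    intervals <- intervals[seq_len(n)]
    artifact <- rep(FALSE, n)
    if (profile$artifact_rate > 0) {
      hit <- which(runif(n) < profile$artifact_rate)
      if (length(hit)) {
        halve <- runif(length(hit)) < 0.5
        intervals[hit] <- intervals[hit] * ifelse(halve, 0.5, 2)
        artifact[hit] <- TRUE
      }
    }
    new_rr_series(cumsum(intervals) / 1000, intervals, artifact,
                  start_age_h = start_age_h)
  })
}

# low-level constructor; validates the RRSeries invariants
new_rr_series <- function(time_s, interval_ms, artifact = NULL,
                          start_age_h = 0) {
  artifact <- artifact %||% rep(FALSE, length(interval_ms))
  stopifnot(length(time_s) == length(interval_ms),
            length(artifact) == length(interval_ms))
  if (any(diff(time_s) <= 0)) {
    abort("Beat times must be strictly increasing.",
          class = "neohrv_invalid_spec")
  }
  if (any(interval_ms <= 0)) {
    abort("Intervals must be positive.", class = "neohrv_invalid_spec")
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        interval_ms = as.numeric(interval_ms),
                        artifact = as.logical(artifact))
  attr(out, "start_age_h") <- start_age_h
  class(out) <- c("rr_series", class(out))
  out
}

#' Simulate clinical covariates for a two-group cohort
#'
#' Draws one row per subject from the group-specific distributions in a
#' pair of [clinical_profile()]s. Covariates are sampled independently
#' within group; missing values are inserted completely at random
#' according to each profile's `missingness` probabilities.
#'
#' @param profiles Named list with `mild` and `severe`
#'   [clinical_profile()] elements.
#' @param n_per_group Number of subjects per group (at least 1).
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   (0 normal-mild / 1 moderate-severe) and the covariate columns
#'   `intrapartum_complications`, `foetal_distress`, `ga_weeks`,
#'   `emergency_delivery`, `male`, `bw_g`, `apgar1`, `apgar5`,
#'   `ventilation_10min`, `ph`, `lactate`, `base_deficit`, `cooled`,
#'   `asm_before_epoch`. Binary covariates are encoded 0/1.
#' @export
simulate_clinical <- function(profiles, n_per_group, seed = NULL) {
  if (!is.numeric(n_per_group) || n_per_group < 1) {
    abort("`n_per_group` must be at least 1.", class = "neohrv_invalid_spec")
  }
  stopifnot(inherits(profiles$mild, "clinical_profile"),
            inherits(profiles$severe, "clinical_profile"))
  n_per_group <- as.integer(n_per_group)
  with_seed_if(seed, {
    rows <- purrr::map2(profiles[c("mild", "severe")], c(0L, 1L),
                        function(p, g) sample_clinical_group(p, g, n_per_group))
    out <- dplyr::bind_rows(rows)
    out$subject_id <- sprintf("S%04d", seq_len(nrow(out)))
    dplyr::relocate(out, "subject_id", "group")
  })
}

rapgar <- function(n, mean, sd) {
  pmin(pmax(round(rnorm(n, mean, sd)), 0), 10)
}

sample_clinical_group <- function(p, group, n) {
  out <- tibble::tibble(
    group = rep(group, n),
    intrapartum_complications = rbinom(n, 1, p$complication_prob),
    foetal_distress = rbinom(n, 1, p$foetal_distress_prob),
    ga_weeks = round(rnorm(n, p$ga_mean, p$ga_sd), 1),
    emergency_delivery = rbinom(n, 1, p$emergency_delivery_prob),
    male = rbinom(n, 1, p$male_prob),
    bw_g = round(rnorm(n, p$bw_mean, p$bw_sd)),
    apgar1 = rapgar(n, p$apgar1_mean, p$apgar1_sd),
    apgar5 = rapgar(n, p$apgar5_mean, p$apgar5_sd),
    ventilation_10min = rbinom(n, 1, p$ventilation_prob),
    ph = round(rnorm(n, p$ph_mean, p$ph_sd), 2),
    lactate = round(rnorm(n, p$lactate_mean, p$lactate_sd), 1),
    base_deficit = round(rnorm(n, p$base_deficit_mean, p$base_deficit_sd), 1),
    cooled = rbinom(n, 1, p$cooled_prob),
    asm_before_epoch = rbinom(n, 1, p$asm_prob)
  )
  for (v in names(p$missingness)) {
    if (!v %in% names(out)) next
    gone <- runif(n) < p$missingness[[v]]
    out[[v]][gone] <- NA
  }
  out
}

#' Simulate a full synthetic cohort (RR epochs plus clinical table)
#'
#' Generates, deterministically for a given `spec$seed`, the clinical
#' covariate table and one RR epoch per subject, sharing subject
#' identifiers. Each subject's RR dynamics are drawn from the group
#' profile with log-normal between-subject jitter on the mean NN level,
#' sinusoid amplitudes and noise SD (`spec$subject_cv`), so features
#' overlap between groups as they do in real cohorts rather than
#' separating perfectly. The RR epoch is stored in an `rr` list-column
#' so the cohort pipes directly into [extract_features()].
#'
#' @param spec A [cohort_spec()].
#'
#' @return A tibble with the clinical columns of [simulate_clinical()]
#'   and an `rr` list-column of `rr_series` tibbles.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_per_group = 2,
#'                                       epoch_duration_s = 600, seed = 7))
#' cohort$subject_id
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a `cohort_spec`.", class = "neohrv_invalid_spec")
  }
  with_seed_if(spec$seed, {
    clin <- simulate_clinical(spec$clinical_profiles, spec$n_per_group)
    prof <- list(`0` = spec$group_profiles$mild,
                 `1` = spec$group_profiles$severe)
    cv <- spec$subject_cv
    clin$rr <- purrr::map(clin$group, function(g) {
      p <- prof[[as.character(g)]]
      pj <- group_profile(
        label = p$label,
        mean_nn_ms = p$mean_nn_ms * exp(rnorm(1, 0, cv$mean_nn)),
        lf_amp_ms = p$lf_amp_ms * exp(rnorm(1, 0, cv$amp)),
        hf_amp_ms = p$hf_amp_ms * exp(rnorm(1, 0, cv$amp)),
        lf_freq_hz = p$lf_freq_hz, hf_freq_hz = p$hf_freq_hz,
        noise_sd_ms = p$noise_sd_ms * exp(rnorm(1, 0, cv$noise)),
        noise_ar1 = p$noise_ar1, artifact_rate = p$artifact_rate)
      simulate_rr(pj, duration_s = spec$epoch_duration_s)
    })
    clin
  })
}
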