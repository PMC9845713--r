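#' Generating profile for one group's RR-interval dynamics
#'
#' A `group_profile` describes the beat-interval dynamics of one outcome
#' group in a synthetic cohort. Intervals are modelled directly as a mean
#' NN level plus low-frequency (LF) and high-frequency (HF) sinusoidal
#' modulation plus AR(1) broadband noise; a fraction of beats is corrupted
#' into ectopic (halved) or missed (doubled) intervals to emulate
#' detection artifacts.
#'
#' @param label Group label: 0 for the normal-mild EEG group, 1 for the
#'   moderate-severe group.
#' @param mean_nn_ms Mean NN interval in ms (must be positive).
#' @param lf_amp_ms,hf_amp_ms Amplitudes (ms) of the LF and HF sinusoidal
#'   components.
#' @param lf_freq_hz,hf_freq_hz Centre frequencies (Hz) of the two
#'   components; `lf_freq_hz` must be below `hf_freq_hz`.
#' @param noise_sd_ms Marginal standard deviation (ms) of the AR(1)
#'   beat-to-beat noise.
#' @param noise_ar1 Lag-1 autocorrelation of the noise, in (-1, 1).
#' @param artifact_rate Expected fraction of corrupted beats, in [0, 0.5).
#' @param sd_nn_ms Approximate overall beat-to-beat SD implied by the
#'   profile; recorded for reference, derived from the components when
#'   `NULL`.
#'
#' @return A list of class `group_profile`.
#' @seealso [default_group_profiles()], [simulate_rr()]
#' @export
group_profile <- function(label,
                          mean_nn_ms,
                          lf_amp_ms = 20,
                          hf_amp_ms = 3,
                          lf_freq_hz = 0.1,
                          hf_freq_hz = 0.8,
                          noise_sd_ms = 10,
                          noise_ar1 = 0.5,
                          artifact_rate = 0.02,
                          sd_nn_ms = NULL) {
  if (!label %in% c(0, 1)) {
    abort("`label` must be 0 (normal-mild) or 1 (moderate-severe).",
          class = "neohrv_invalid_spec")
  }
  assert_scalar_number(mean_nn_ms, "mean_nn_ms", lower = 1e-8)
  assert_scalar_number(lf_amp_ms, "lf_amp_ms", lower = 0)
  assert_scalar_number(hf_amp_ms, "hf_amp_ms", lower = 0)
  assert_scalar_number(lf_freq_hz, "lf_freq_hz", lower = 1e-6)
  assert_scalar_number(hf_freq_hz, "hf_freq_hz", lower = 1e-6)
  if (lf_freq_hz >= hf_freq_hz) {
    abort("`lf_freq_hz` must be below `hf_freq_hz`.",
          class = "neohrv_invalid_spec")
  }
  assert_scalar_number(noise_sd_ms, "noise_sd_ms", lower = 0)
  assert_scalar_number(noise_ar1, "noise_ar1", lower = -0.999, upper = 0.999)
  if (!is.numeric(artifact_rate) || artifact_rate < 0 || artifact_rate >= 0.5) {
    abort("`artifact_rate` must be in [0, 0.5).", class = "neohrv_invalid_spec")
  }
  if (is.null(sd_nn_ms)) {
    sd_nn_ms <- sqrt(lf_amp_ms^2 / 2 + hf_amp_ms^2 / 2 + noise_sd_ms^2)
  }
  structure(
    list(label = as.integer(label), mean_nn_ms = mean_nn_ms,
         sd_nn_ms = sd_nn_ms, lf_amp_ms = lf_amp_ms, hf_amp_ms = hf_amp_ms,
         lf_freq_hz = lf_freq_hz, hf_freq_hz = hf_freq_hz,
         noise_sd_ms = noise_sd_ms, noise_ar1 = noise_ar1,
         artifact_rate = artifact_rate),
    class = "group_profile"
  )
}

#' Default group profiles for the two EEG-grade groups
#'
#' The two profiles encode the group contrasts reported for early HRV in
#' neonatal encephalopathy: the moderate-severe group has a longer mean NN
#' interval (slower heart rate), a lower LF/HF spectral balance, a
#' narrower interval histogram and smoother, less complex beat-to-beat
#' dynamics (lower multiscale-entropy maximum, area under the curve and
#' short-scale slope).
#'
#' The complexity contrast is carried by the noise process. The mild
#' profile has a large, strongly autocorrelated noise component: a
#' high-amplitude, unpredictable low-frequency wander that keeps sample
#' entropy high at every smoothing scale while adding little power to the
#' HF band (so the LF/HF balance stays high). The severe profile instead
#' concentrates its residual variability in a regular oscillation near
#' the beat-to-beat Nyquist plus a small anti-persistent noise floor;
#' both live at the shortest time scales, so its entropy starts lower and
#' collapses quickly under the moving-average coarse-graining, giving the
#' lower entropy maximum, area and short-scale slope. Mean NN levels and
#' sinusoid amplitudes are set so group-median band powers and mean NN
#' sit near the reported group medians.
#'
#' @return A named list with elements `mild` (label 0) and `severe`
#'   (label 1), each a [group_profile()].
#' @export
default_group_profiles <- function() {
  list(
    mild = group_profile(
      label = 0, mean_nn_ms = 525,
      lf_amp_ms = 23, hf_amp_ms = 1.5,
      lf_freq_hz = 0.1, hf_freq_hz = 0.8,
      noise_sd_ms = 25, noise_ar1 = 0.95,
      artifact_rate = 0.02
    ),
    severe = group_profile(
      label = 1, mean_nn_ms = 590,
      lf_amp_ms = 20, hf_amp_ms = 10,
      lf_freq_hz = 0.1, hf_freq_hz = 0.8,
      noise_sd_ms = 2.5, noise_ar1 = -0.5,
      artifact_rate = 0.02
    )
  )
}

#' Generating distributions for one group's clinical covariates
#'
#' Encodes, for a single outcome group, the sampling distributions of the
#' perinatal covariates used by the risk models: gestational age, birth
#' weight, sex, delivery circumstances, Apgar scores, assisted ventilation
#' at 10 minutes, blood-gas measures, plus cooling and anti-seizure
#' medication flags used for subgroup analyses. Apgar scores are drawn
#' from a rounded normal clipped to 0-10. Missing values are inserted
#' completely at random with per-covariate probabilities.
#'
#' @param apgar1_mean,apgar1_sd,apgar5_mean,apgar5_sd Latent normal mean
#'   and SD for the Apgar scores before rounding/clipping to 0-10.
#' @param ventilation_prob Probability of assisted ventilation at 10 min.
#' @param emergency_delivery_prob Probability of emergency delivery
#'   (assisted vaginal or emergency caesarean).
#' @param foetal_distress_prob Probability of suspected foetal distress.
#' @param complication_prob Probability of any intrapartum complication.
#' @param male_prob Probability of male sex.
#' @param cooled_prob Probability of therapeutic hypothermia.
#' @param asm_prob Probability of anti-seizure medication before the
#'   analysed epoch.
#' @param ga_mean,ga_sd Gestational age at birth (weeks).
#' @param bw_mean,bw_sd Birth weight (g).
#' @param ph_mean,ph_sd Lowest cord pH.
#' @param lactate_mean,lactate_sd First postnatal lactate (mmol/L).
#' @param base_deficit_mean,base_deficit_sd First postnatal base deficit
#'   (mmol/L).
#' @param missingness Named numeric vector of per-covariate missingness
#'   probabilities (names must be covariate column names).
#'
#' @return A list of class `clinical_profile`.
#' @seealso [default_clinical_profiles()], [simulate_clinical()]
#' @export
clinical_profile <- function(apgar1_mean, apgar1_sd,
                             apgar5_mean, apgar5_sd,
                             ventilation_prob,
                             emergency_delivery_prob,
                             foetal_distress_prob,
                             complication_prob = 0.86,
                             male_prob = 0.62,
                             cooled_prob = 0.8,
                             asm_prob = 0.15,
                             ga_mean = 40.2, ga_sd = 1.2,
                             bw_mean = 3475, bw_sd = 600,
                             ph_mean = 7.0, ph_sd = 0.18,
                             lactate_mean = 11.9, lactate_sd = 4.3,
                             base_deficit_mean = 15.8, base_deficit_sd = 5.6,
                             missingness = NULL) {
  probs <- c(ventilation_prob = ventilation_prob,
             emergency_delivery_prob = emergency_delivery_prob,
             foetal_distress_prob = foetal_distress_prob,
             complication_prob = complication_prob,
             male_prob = male_prob, cooled_prob = cooled_prob,
             asm_prob = asm_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must be in [0, 1].",
          class = "neohrv_invalid_spec")
  }
  sds <- c(apgar1_sd, apgar5_sd, ga_sd, bw_sd, ph_sd, lactate_sd,
           base_deficit_sd)
  if (any(sds < 0)) {
    abort("All standard deviations must be non-negative.",
          class = "neohrv_invalid_spec")
  }
  missingness <- missingness %||% numeric(0)
  if (length(missingness) &&
      (any(missingness < 0 | missingness > 1) || is.null(names(missingness)))) {
    abort("`missingness` must be a named vector of probabilities in [0, 1].",
          class = "neohrv_invalid_spec")
  }
  structure(
    list(apgar1_mean = apgar1_mean, apgar1_sd = apgar1_sd,
         apgar5_mean = apgar5_mean, apgar5_sd = apgar5_sd,
         ventilation_prob = ventilation_prob,
         emergency_delivery_prob = emergency_delivery_prob,
         foetal_distress_prob = foetal_distress_prob,
         complication_prob = complication_prob,
         male_prob = male_prob, cooled_prob = cooled_prob,
         asm_prob = asm_prob,
         ga_mean = ga_mean, ga_sd = ga_sd,
         bw_mean = bw_mean, bw_sd = bw_sd,
         ph_mean = ph_mean, ph_sd = ph_sd,
         lactate_mean = lactate_mean, lactate_sd = lactate_sd,
         base_deficit_mean = base_deficit_mean,
         base_deficit_sd = base_deficit_sd,
         missingness = missingness),
    class = "clinical_profile"
  )
}

#' Default clinical profiles for the two EEG-grade groups
#'
#' Group-wise distributions approximating the published cohort summaries:
#' the moderate-severe group has lower Apgar scores, more assisted
#' ventilation at 10 minutes, fewer emergency deliveries, lower cord pH,
#' higher lactate and base deficit, and near-universal therapeutic
#' hypothermia. Default missingness mirrors the reported missing-data
#' counts (foetal distress 11.7%, Apgar scores 3.3%, ventilation 1.7%,
#' pH 15%, lactate 29.2%, base deficit 25.8%). The summaries are medians
#' and IQRs, so these distributions are pragmatic approximations rather
#' than calibrated fits.
#'
#' @return A named list with elements `mild` and `severe`, each a
#'   [clinical_profile()].
#' @export
default_clinical_profiles <- function() {
  miss <- c(foetal_distress = 0.117, apgar1 = 0.033, apgar5 = 0.033,
            ventilation_10min = 0.017, ph = 0.15, lactate = 0.292,
            base_deficit = 0.258)
  list(
    mild = clinical_profile(
      apgar1_mean = 2.5, apgar1_sd = 1.9,
      apgar5_mean = 5.3, apgar5_sd = 2.1,
      ventilation_prob = 0.415,
      emergency_delivery_prob = 0.741,
      foetal_distress_prob = 0.816,
      complication_prob = 0.852,
      male_prob = 0.593, cooled_prob = 0.611, asm_prob = 0,
      ga_mean = 40.4, ga_sd = 1.1,
      bw_mean = 3525, bw_sd = 492,
      ph_mean = 7.05, ph_sd = 0.15,
      lactate_mean = 10.9, lactate_sd = 3.2,
      base_deficit_mean = 14.6, base_deficit_sd = 4.5,
      missingness = miss
    ),
    severe = clinical_profile(
      apgar1_mean = 1.2, apgar1_sd = 1.5,
      apgar5_mean = 2.8, apgar5_sd = 2.0,
      ventilation_prob = 0.892,
      emergency_delivery_prob = 0.530,
      foetal_distress_prob = 0.684,
      complication_prob = 0.864,
      male_prob = 0.652, cooled_prob = 0.970, asm_prob = 0.288,
      ga_mean = 40.0, ga_sd = 1.2,
      bw_mean = 3434, bw_sd = 689,
      ph_mean = 6.95, ph_sd = 0.20,
      lactate_mean = 13.0, lactate_sd = 5.2,
      base_deficit_mean = 17.0, base_deficit_sd = 6.4,
      missingness = miss
    )
  )
}

#' Specification of a full synthetic cohort
#'
#' Bundles the per-group RR and clinical profiles with the cohort size,
#' epoch duration and seed so a whole two-group cohort can be generated
#' reproducibly with [simulate_cohort()].
#'
#' @param n_per_group Number of subjects in each group (at least 1).
#' @param group_profiles List with elements `mild` and `severe`
#'   ([group_profile()] objects).
#' @param clinical_profiles List with elements `mild` and `severe`
#'   ([clinical_profile()] objects).
#' @param epoch_duration_s Duration of each subject's RR epoch in seconds
#'   (at least 600; default 3600, one hour).
#' @param seed Integer seed controlling the whole cohort.
#' @param subject_cv Between-subject heterogeneity: named list of
#'   log-normal coefficients of variation applied per subject to the
#'   group profile's `mean_nn_ms` (`mean_nn`), sinusoid amplitudes
#'   (`amp`) and `noise_sd_ms` (`noise`). The defaults (0.09, 0.3, 0.25)
#'   reproduce overlapping group distributions of the kind reported for
#'   real cohorts (e.g. mean-NN interquartile ranges of neighbouring
#'   groups overlap); set all to 0 for identical subjects within group.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group,
                        group_profiles = default_group_profiles(),
                        clinical_profiles = default_clinical_profiles(),
                        epoch_duration_s = 3600,
                        seed = 1L,
                        subject_cv = list(mean_nn = 0.09, amp = 0.3,
                                          noise = 0.25)) {
  if (!is.numeric(n_per_group) || n_per_group < 1) {
    abort("`n_per_group` must be at least 1.", class = "neohrv_invalid_spec")
  }
  if (epoch_duration_s < 600) {
    abort("`epoch_duration_s` must be at least 600 s.",
          class = "neohrv_invalid_spec")
  }
  stopifnot(inherits(group_profiles$mild, "group_profile"),
            inherits(group_profiles$severe, "group_profile"),
            inherits(clinical_profiles$mild, "clinical_profile"),
            inherits(clinical_profiles$severe, "clinical_profile"))
  subject_cv <- utils::modifyList(list(mean_nn = 0.09, amp = 0.3,
                                       noise = 0.25), subject_cv)
  if (any(unlist(subject_cv) < 0)) {
    abort("`subject_cv` entries must be non-negative.",
          class = "neohrv_invalid_spec")
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         group_profiles = group_profiles,
         clinical_profiles = clinical_profiles,
         epoch_duration_s = epoch_duration_s,
         seed = as.integer(seed),
         subject_cv = subject_cv),
    class = "cohort_spec"
  )
}
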