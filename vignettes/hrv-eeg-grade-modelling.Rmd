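---
title: "Modelling early EEG severity in neonatal encephalopathy from heart rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling early EEG severity in neonatal encephalopathy from heart rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neohrv)
```

## The problem

In hypoxic-ischaemic encephalopathy (HIE), the severity of the EEG
background in the first hours of life is one of the strongest early
markers of brain injury, but continuous EEG review requires equipment
and expertise that many units do not have. The ECG, by contrast, is
monitored almost everywhere. Because the autonomic nervous system is
depressed in proportion to the encephalopathy, heart rate variability
(HRV) extracted from an early one-hour ECG epoch carries information
about the EEG grade: infants with moderate-severe EEG backgrounds tend
to have a longer mean interbeat (NN) interval, a lower LF/HF spectral
balance, a narrower NN histogram and less complex beat-to-beat dynamics.

`neohrv` implements that analysis end to end: RR preprocessing, HRV
feature extraction, univariable screening, and multivariable logistic
risk models (HRV-only, clinical-only and combined) evaluated by AUROC,
a Youden operating point and the Hosmer-Lemeshow test. It also ships a
synthetic cohort generator so the whole pipeline is testable without
access to clinical recordings, which cannot be shared.

## Pipeline and model

1. **Preprocessing.** R peaks are detected with a Pan-Tompkins-style
   detector (5-30 Hz zero-phase band-pass, squared and smoothed energy,
   adaptive per-block threshold, 200 ms refractory period). Beats whose
   interval leaves the 200-1200 ms physiologic gate or deviates by more
   than 30% from the 11-beat running median are flagged as artifact.
   These automated rules stand in for the visual artifact review used on
   clinical data; both thresholds are configurable and surfaced in the
   run configuration. The earliest one-hour epoch ending before 12 h of
   postnatal age is selected and tiled into 300-s segments at 150-s
   steps (50% overlap). A segment is dropped when more than half of its
   *covered time* is flagged; measuring artifact in time rather than
   beats weighs missed-beat artifacts correctly.

2. **Features.** Per segment, on unflagged beats:
   *time domain* - mean NN (ms), SDNN (ms), and TINN, the base width of
   the best least-squares triangular fit to the NN histogram at the
   conventional 1/128 s (7.8125 ms) bin width;
   *frequency domain* - the tachogram is cubic-spline resampled at 4 Hz,
   mean-subtracted, and a Welch periodogram (120-s Hann windows, 50%
   overlap, variance-preserving scaling) is integrated over VLF
   (0.01-0.04 Hz), LF (0.04-0.2 Hz) and HF (0.2-2 Hz) bands, with
   LF/HF their ratio;
   *complexity* - sample entropy (embedding dimension m = 2, tolerance
   r = 0.15 x the scale-1 SD, Chebyshev distance, self-matches excluded,
   nats) on moving-average smoothed copies of the segment at scales
   1-20, summarised by the curve's trapezoidal area (complexity index),
   maximum, and least-squares slopes over scales 1-5 and 6-20.
   Each feature is summarised as the **median over retained segments**;
   the LF/HF ratio is the median of per-segment ratios, not the ratio of
   medians.

3. **Modelling.** Positively skewed features (SDNN, TINN, the three band
   powers, LF/HF) are log10-transformed; all features are then z-scored
   so odds ratios are per 1 SD. Every HRV feature and clinical covariate
   is screened univariably; predictors with p < 0.25 are eligible, and
   within pairs correlated above |r| = 0.8 only the higher univariable
   AUROC survives. The three multivariable logistic models are fitted by
   maximum likelihood on the complete-case subset shared by all terms,
   and evaluated by AUROC with a DeLong 95% CI, the Youden-optimal
   cutoff (with sensitivity, specificity, PPV, NPV) and the
   Hosmer-Lemeshow deciles-of-risk test. The three published model
   equations are also available verbatim through `published_model()` for
   application to new data.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Artifact range gate | 200-1200 | ms | physiologic neonatal interval range |
| Running-median deviation | 0.30 | fraction | flags ectopic/missed beats at half/double spacing |
| Segment length / step | 300 / 150 | s | five-minute segments, 50% overlap |
| Segment artifact budget | 0.5 | time fraction | segments mostly artifact carry no usable signal |
| Resampling rate | 4 | Hz | twice the 2 Hz HF upper edge |
| Welch window | 120 | s | resolves the 0.01 Hz VLF lower edge within a 300-s segment |
| SampEn m / r | 2 / 0.15 x SD | - | standard HRV convention |
| MSE scales | 1-20 | beats | short (1-5) and long (6-20) slope ranges |
| TINN bin width | 7.8125 | ms | 1/128 s HRV Task Force convention |
| Screening p | 0.25 | - | permissive eligibility for multivariable entry |
| Correlation pruning | 0.8 | \|Pearson r\| | drops near-duplicate predictors |

## Design choices that were genuinely open

* **Band definitions.** Fast neonatal respiration moves HF activity
  well above the adult band, so the default bands are the neonatal ones
  (HF 0.2-2 Hz, LF 0.04-0.2 Hz, VLF 0.01-0.04 Hz); the adult Task-Force
  preset (HF 0.15-0.4 Hz) is available via
  `spectral_bands("taskforce")`. The HF upper edge may sit exactly at
  the resampled Nyquist because band integration is half-open and never
  counts the Nyquist bin.
* **"Mean NN".** Interpreted as the mean of normal-to-normal intervals
  (artifact-excluded RR), the standard HRV meaning; no amplitude
  normalisation is applied.
* **MSE coarse-graining.** A moving-average filter *without* decimation
  is the default; classic decimating coarse-graining is available with
  `mse_config(decimate = TRUE)`. The tolerance r is fixed from the
  scale-1 SD for all scales (the standard MSE convention);
  `r_per_scale = TRUE` recomputes it per scale. Entropies are in nats.
* **PSD estimator.** Welch on the evenly resampled tachogram. The
  estimator is calibrated: a pure sinusoid of amplitude A integrates to
  A^2/2 within 5%, and band powers of white noise sum to the signal
  variance.
* **Complexity index.** Trapezoidal integration over scales 1-20, so a
  flat curve at c has area 19c.
* **AUROC CI.** DeLong by default; the Hanley-McNeil normal
  approximation is available (`ci_method = "hanley"`). Wald CIs are used
  for odds ratios, matching intervals that are symmetric on the log
  scale.
* **Youden ties.** Among cutoffs maximizing sensitivity + specificity -
  1, the highest-specificity one is returned (predicted positive means
  score >= cutoff).
* **Hosmer-Lemeshow.** Deciles of risk with
  chi^2 = sum (O-E)^2 / (E(1-E/n_g)) on g - 2 degrees of freedom; tied
  quantiles merge groups with a warning, and g = 2 is rejected because
  it leaves no degrees of freedom.
* **Degenerate inputs.** Constant series have zero SDNN, TINN of at most
  one bin and zero entropy at every scale; a model with no eligible
  terms falls back to the prevalence and an AUROC of 0.5; undefined
  entropies (no template matches) propagate as missing values that
  median aggregation skips.

## What the synthetic generator emulates

Each subject's epoch is generated directly in interval space:
mean NN level plus LF and HF sinusoids (random phases) plus AR(1)
noise, clipped to 200-2000 ms, with a configurable fraction of beats
corrupted into halved (ectopic) or doubled (missed) detections. An
interval-space model is simpler than integral-pulse-frequency
modulation and sufficient to realise the band-power and entropy
contrasts the downstream analysis consumes.

The two default group profiles encode the documented contrasts:
the moderate-severe group is slower (mean NN 590 vs 525 ms), has a
lower LF/HF balance, a narrower histogram and less complex dynamics.
The complexity contrast needs care under fixed-tolerance moving-average
MSE, where every curve decays with scale: the mild profile carries a
large, strongly autocorrelated noise component (SD 25 ms, lag-1
correlation 0.95) - unpredictable at the beat scale yet concentrated at
low frequency, so entropy stays high at every scale while the HF band
stays quiet; the severe profile concentrates its residual variability
in a regular oscillation near the beat-to-beat Nyquist (10 ms at
0.8 Hz) plus a small anti-persistent noise floor (SD 2.5 ms, lag-1
correlation -0.5), content that short-scale smoothing annihilates, so
its curve starts lower and collapses faster - yielding the lower
maximum, area and short-scale slope. The margins on the two MSE
contrasts (maximum and short-scale slope) are modest, roughly twice the
sampling error of a 100-subject group median, and are the fragile part
of the default calibration.

Subjects within a group are not identical: log-normal between-subject
jitter (CV 0.09 on mean NN, 0.3 on amplitudes, 0.25 on noise SD, sized
from the spread of reported group interquartile ranges) makes the group
feature distributions overlap as real cohorts do - without it
within-group features are nearly constant and evaluation becomes
vacuous. Even with jitter, the default contrast is strong enough that
the HRV model separates a default cohort perfectly in-sample (the fit
warns about quasi-separation); the generator prioritises unambiguous
group directions over matching any particular discrimination level.
Clinical covariates are sampled independently within group from
distributions approximating the reported cohort summaries (lower Apgar
scores, more ventilation, lower pH in the severe group), with
missingness inserted completely at random at the reported per-covariate
rates. Only medians and IQRs are reported for the real cohort, so these
distributions are approximations, not calibrated fits.

What passing on synthetic data shows - and does not. The generator
provides exact ground truth for beat times, artifact locations, band
powers and group membership, so it validates the *machinery*: detector
accuracy, artifact-rule recovery, spectral calibration, entropy
estimation, screening calibration under the null, parameter recovery
and the evaluation statistics. It does not validate clinical
transportability: real neonatal ECG contains nonstationarity, cooling
and medication effects, correlated covariates and artifact structure
that the generator does not model, and no synthetic result substitutes
for the published models' performance on real infants.

## Problem sizes used by the test suite

Simulation-based checks are sized to be decisive yet quick: the
end-to-end direction check uses 100 subjects per group with full
one-hour epochs; null-contrast screening calibration uses 60 cohorts of
20 per group with 10-minute epochs (entropy features off, since the
null concerns the screen); the entropy oracle comparison uses 500
series up to length 200; logistic parameter recovery uses 100
replicates at n = 5000; the Hosmer-Lemeshow type-I check uses 200
replicates at n = 500. These sizes are the package's own choices and
are stated here so they can be scaled up when more compute is at hand.

## Known limitations

* The artifact rules are a stand-in for human review; their thresholds
  were chosen for the synthetic artifact model (halved/doubled beats)
  and should be re-examined on real recordings.
* Reported model performance on synthetic cohorts is apparent (fit and
  evaluated on the same subjects); no cross-validation or optimism
  correction is implemented, mirroring the published analysis.
* The published equations carry coefficients rounded to two decimals;
  probabilities derived from them inherit that rounding.
* ECG ingestion is limited to plain-text sample series and two-column
  RR tables; waveform-container parsing (EDF/WFDB) is out of scope.
* Whether the original in-house software decimated after the moving
  average, and whether its entropies were in nats, is not stated in the
  source material; both choices are explicit flags here rather than
  silent assumptions.
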