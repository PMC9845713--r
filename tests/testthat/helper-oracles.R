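# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# O(N^2) sample-entropy oracle via full pairwise distance matrices:
# templates of length m and m+1 both start at positions 1..n-m,
# Chebyshev distance, self-matches excluded.
sampen_oracle <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  if (nt < 2) return(NA_real_)
  match_all <- matrix(TRUE, nt, nt)
  for (k in 0:(m - 1)) {
    seg <- x[(1 + k):(nt + k)]
    match_all <- match_all & (abs(outer(seg, seg, "-")) <= r)
  }
  seg <- x[(1 + m):(nt + m)]
  match_ext <- match_all & (abs(outer(seg, seg, "-")) <= r)
  B <- (sum(match_all) - nt) / 2
  A <- (sum(match_ext) - nt) / 2
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# least-squares slope by the closed-form normal equations
slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# exhaustive Youden scan: best J over all observed cutoffs, ties broken
# towards the higher specificity
youden_oracle <- function(scores, labels) {
  cand <- sort(unique(scores))
  best <- c(j = -Inf, spec = -Inf, cutoff = NA_real_)
  for (cut in cand) {
    pos <- scores >= cut
    sens <- sum(pos & labels == 1) / sum(labels == 1)
    spec <- sum(!pos & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best["j"] + 1e-12 ||
        (abs(j - best["j"]) <= 1e-12 && spec > best["spec"])) {
      best <- c(j = j, spec = spec, cutoff = cut)
    }
  }
  best
}

# noise-free generating profile for exact-value tests
quiet_profile <- function(mean_nn = 500, ...) {
  group_profile(0, mean_nn_ms = mean_nn, lf_amp_ms = 0, hf_amp_ms = 0,
                noise_sd_ms = 0, artifact_rate = 0, ...)
}

# synthetic single-lead ECG: Gaussian QRS-like bumps at known beat times
make_ecg <- function(n_beats = 100, interval_s = 0.5, fs = 250,
                     noise_sd = 0) {
  t_peaks <- seq(interval_s, by = interval_s, length.out = n_beats)
  n <- ceiling((max(t_peaks) + 0.5) * fs)
  ecg <- numeric(n)
  w <- round(0.012 * fs)
  bump <- exp(-(seq(-w, w) / (0.004 * fs))^2)
  for (i in round(t_peaks * fs)) {
    ecg[(i - w):(i + w)] <- ecg[(i - w):(i + w)] + bump
  }
  if (noise_sd > 0) ecg <- ecg + rnorm(n, sd = noise_sd)
  list(ecg = ecg, fs = fs, peaks_s = t_peaks)
}

# constant-interval RR series built by hand (bypasses the simulator)
constant_rr <- function(interval_ms = 500, duration_s = 600,
                        start_age_h = 0) {
  n <- ceiling(duration_s * 1000 / interval_ms)
  iv <- rep(interval_ms, n)
  out <- tibble::tibble(time_s = cumsum(iv) / 1000, interval_ms = iv,
                        artifact = FALSE)
  attr(out, "start_age_h") <- start_age_h
  class(out) <- c("rr_series", class(out))
  out
}
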