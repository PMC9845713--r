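#' Spectral band definitions for the neonatal tachogram
#'
#' The default (`"neonatal"`) preset uses bands appropriate for the fast
#' neonatal respiratory rate: VLF 0.01-0.04 Hz, LF 0.04-0.2 Hz and HF
#' 0.2-2 Hz. The adult Task-Force convention (VLF 0.003-0.04, LF
#' 0.04-0.15, HF 0.15-0.4 Hz) is available as `"taskforce"`. The
#' resampling rate must exceed twice the HF upper edge.
#'
#' @param preset `"neonatal"` (default) or `"taskforce"`.
#' @param resample_hz Tachogram resampling rate in Hz (default 4).
#'
#' @return A list of class `spectral_bands` with elements `vlf`, `lf`,
#'   `hf` (two-element `c(lower, upper)` vectors, Hz), `resample_hz` and
#'   `psd_method`.
#' @export
spectral_bands <- function(preset = c("neonatal", "taskforce"),
                           resample_hz = 4) {
  preset <- match.arg(preset)
  b <- switch(preset,
    neonatal  = list(vlf = c(0.01, 0.04), lf = c(0.04, 0.2), hf = c(0.2, 2)),
    taskforce = list(vlf = c(0.003, 0.04), lf = c(0.04, 0.15),
                     hf = c(0.15, 0.4))
  )
  # bands are half-open [lo, hi), so an HF edge exactly at Nyquist is
  # admissible: the Nyquist bin itself is never integrated
  if (resample_hz < 2 * b$hf[2]) {
    abort("`resample_hz` must be at least twice the HF upper edge.",
          class = "neohrv_invalid_spec")
  }
  structure(c(b, list(resample_hz = resample_hz, psd_method = "welch",
                      preset = preset)),
            class = "spectral_bands")
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with Hann-windowed, mean-removed,
#' 50%-overlapping windows. The one-sided PSD is scaled so that summing
#' `psd * df` over all frequency bins recovers the signal variance
#' (Parseval); a pure sinusoid of amplitude A therefore integrates to
#' A^2/2.
#'
#' @param x Numeric signal, uniformly sampled.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds (default 120).
#' @param overlap Fractional window overlap (default 0.5).
#'
#' @return A tibble with columns `freq` (Hz) and `psd` (signal
#'   units^2 per Hz).
#' @export
welch_psd <- function(x, fs, window_s = 120, overlap = 0.5) {
  n <- length(x)
  nw <- min(n, round(window_s * fs))
  if (nw < 8) {
    abort("Signal too short for a Welch estimate.",
          class = "neohrv_insufficient_data")
  }
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))
  U <- sum(w^2)
  nf <- floor(nw / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * U)
    # one-sided: double all bins except DC (and Nyquist when nw is even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nw %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  tibble::tibble(freq = (seq_len(nf) - 1) * fs / nw,
                 psd = acc / length(starts))
}

#' Spectral band powers of a segment's tachogram
#'
#' The unflagged beat intervals are cubic-spline interpolated onto a
#' uniform grid at `bands$resample_hz`, mean-subtracted, and a Welch
#' periodogram (120-s Hann windows, 50% overlap) is integrated over the
#' VLF, LF and HF bands. Powers are in ms^2; the LF/HF ratio is the ratio
#' of the two band integrals.
#'
#' @param time_s,interval_ms Beat times (s) and intervals (ms) of the
#'   unflagged beats of one segment.
#' @param bands A [spectral_bands()] object.
#' @param window_s Welch window length, s.
#'
#' @return A one-row tibble with `vlf_power_ms2`, `lf_power_ms2`,
#'   `hf_power_ms2` and `lf_hf_ratio`.
#' @export
band_powers <- function(time_s, interval_ms, bands = spectral_bands(),
                        window_s = 120) {
  if (!inherits(bands, "spectral_bands")) {
    abort("`bands` must be a `spectral_bands` object.",
          class = "neohrv_invalid_spec")
  }
  fs <- bands$resample_hz
  if (bands$hf[2] > fs / 2 + 1e-12) {
    abort("HF band extends beyond the Nyquist of the resampled tachogram.",
          class = "neohrv_invalid_spec")
  }
  if (length(time_s) < 8 || diff(range(time_s)) < 30) {
    abort("Too few beats for a spectral estimate.",
          class = "neohrv_insufficient_data")
  }
  grid <- seq(min(time_s), max(time_s), by = 1 / fs)
  tach <- spline(time_s, interval_ms, xout = grid, method = "fmm")$y
  tach <- tach - mean(tach)
  psd <- welch_psd(tach, fs, window_s = window_s)
  df <- psd$freq[2] - psd$freq[1]
  bp <- function(b) sum(psd$psd[psd$freq >= b[1] & psd$freq < b[2]]) * df
  vlf <- bp(bands$vlf); lf <- bp(bands$lf); hf <- bp(bands$hf)
  tibble::tibble(vlf_power_ms2 = vlf, lf_power_ms2 = lf,
                 hf_power_ms2 = hf, lf_hf_ratio = lf / hf)
}
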