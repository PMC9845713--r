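#' Sample entropy of a series
#'
#' Sample entropy is `-log(A/B)` where `B` counts pairs of length-`m`
#' templates within Chebyshev distance `r` of each other and `A` counts
#' the subset that still match when extended by one point. Both template
#' sets are drawn from the first `length(x) - m` starting positions,
#' self-matches are excluded, and the result is in nats. `NA` is returned
#' when either count is zero (the statistic is undefined).
#'
#' @param x Numeric series.
#' @param m Embedding dimension (default 2).
#' @param r Match tolerance in the units of `x`; defaults to
#'   `r_factor * sd(x)`.
#' @param r_factor Tolerance as a fraction of the series SD (default
#'   0.15), used when `r` is not given.
#'
#' @return Entropy in nats, or `NA` when undefined.
#' @export
#' @examples
#' sample_entropy(rep(5, 50))          # perfectly regular: 0
#' sample_entropy(rnorm(500))          # white noise: high
sample_entropy <- function(x, m = 2, r = NULL, r_factor = 0.15) {
  if (!is.numeric(x) || length(x) < m + 2) {
    abort("`x` must have at least m + 2 points.",
          class = "neohrv_insufficient_data")
  }
  r <- r %||% (r_factor * sd(x))
  if (is.na(r) || r < 0) {
    abort("`r` must be non-negative.", class = "neohrv_invalid_spec")
  }
  sampen_cpp(as.numeric(x), as.integer(m), r)
}

#' Multiscale-entropy configuration
#'
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a fraction of the scale-1 series SD
#'   (default 0.15). The tolerance is fixed from the scale-1 SD for all
#'   scales unless `r_per_scale` is set.
#' @param scales Scale factors (default 1:20).
#' @param short_scales,long_scales Scale ranges used for the short- and
#'   long-scale slope features (defaults 1:5 and 6:20).
#' @param decimate Coarse-grain with non-overlapping averages (classic
#'   decimating coarse-graining) instead of the default moving-average
#'   filter without decimation.
#' @param r_per_scale Recompute the tolerance from each scale's own SD
#'   instead of fixing it at scale 1.
#'
#' @return A list of class `mse_config`.
#' @export
mse_config <- function(m = 2, r_factor = 0.15, scales = 1:20,
                       short_scales = 1:5, long_scales = 6:20,
                       decimate = FALSE, r_per_scale = FALSE) {
  if (m < 1 || r_factor <= 0 || r_factor >= 1) {
    abort("Require m >= 1 and 0 < r_factor < 1.",
          class = "neohrv_invalid_spec")
  }
  if (max(scales) < max(long_scales)) {
    abort("`scales` must cover the long-scale range.",
          class = "neohrv_invalid_spec")
  }
  structure(list(m = as.integer(m), r_factor = r_factor,
                 scales = as.integer(scales),
                 short_scales = as.integer(short_scales),
                 long_scales = as.integer(long_scales),
                 decimate = decimate, r_per_scale = r_per_scale),
            class = "mse_config")
}

#' Multiscale sample-entropy curve
#'
#' The scale-tau series is the moving average of the raw series with
#' window tau (without decimation by default), and sample entropy is
#' computed at each scale with the tolerance fixed at
#' `r_factor * sd(scale-1 series)`. Scale 1 is the sample entropy of the
#' raw series.
#'
#' @param x Numeric series (one segment's NN intervals).
#' @param cfg An [mse_config()].
#'
#' @return A tibble of class `mse_curve` with columns `scale` and
#'   `entropy` (nats; `NA` where undefined).
#' @export
mse_curve <- function(x, cfg = mse_config()) {
  if (!inherits(cfg, "mse_config")) {
    abort("`cfg` must be an `mse_config`.", class = "neohrv_invalid_spec")
  }
  max_scale <- max(cfg$scales)
  min_len <- if (cfg$decimate) 50 * max_scale else 50 + max_scale - 1
  if (length(x) < min_len) {
    abort(sprintf(
      "Series of %d points is too short for scale %d (need >= %d).",
      length(x), max_scale, min_len), class = "neohrv_insufficient_data")
  }
  r1 <- cfg$r_factor * sd(x)
  ent <- vapply(cfg$scales, function(tau) {
    y <- if (tau == 1) x else {
      ma <- as.numeric(stats::filter(x, rep(1 / tau, tau), sides = 1))
      ma <- ma[!is.na(ma)]
      if (cfg$decimate) ma[seq(1, length(ma), by = tau)] else ma
    }
    r <- if (cfg$r_per_scale) cfg$r_factor * sd(y) else r1
    sampen_cpp(y, cfg$m, r)
  }, numeric(1))
  out <- tibble::tibble(scale = cfg$scales, entropy = ent)
  class(out) <- c("mse_curve", class(out))
  out
}

#' Summary features of a multiscale-entropy curve
#'
#' Computes the four curve features used by the risk models: the
#' complexity index (trapezoidal area under the curve across all scales),
#' the maximum entropy, and the least-squares slopes of the curve over
#' the short- and long-scale ranges.
#'
#' @param curve A tibble with `scale` and `entropy` columns, as from
#'   [mse_curve()].
#' @param short_scales,long_scales Scale ranges for the two slopes.
#'
#' @return A one-row tibble with `mse_complexity_index`, `mse_max`,
#'   `mse_short_slope` and `mse_long_slope`. A feature is `NA` when the
#'   entropy is undefined at any scale it requires.
#' @export
mse_features <- function(curve, short_scales = 1:5, long_scales = 6:20) {
  stopifnot(all(c("scale", "entropy") %in% names(curve)))
  s <- curve$scale; e <- curve$entropy
  trapz <- function(xs, ys) sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  ci <- if (anyNA(e)) NA_real_ else trapz(s, e)
  mx <- if (anyNA(e)) NA_real_ else max(e)
  slope_over <- function(rng) {
    i <- s %in% rng
    if (sum(i) < 2 || anyNA(e[i])) return(NA_real_)
    unname(coef(lm(e[i] ~ s[i]))[2])
  }
  tibble::tibble(mse_complexity_index = ci, mse_max = mx,
                 mse_short_slope = slope_over(short_scales),
                 mse_long_slope = slope_over(long_scales))
}
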