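#' AUROC with confidence interval
#'
#' Area under the ROC curve — equivalently the Mann-Whitney probability
#' that a random positive scores above a random negative, with ties
#' counted 1/2 — with a 95% CI by the DeLong method (default) or the
#' Hanley-McNeil normal approximation.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels (0/1); both classes must be present.
#' @param ci_method `"delong"` (default) or `"hanley"`.
#'
#' @return A one-row tibble: `auroc`, `conf.low`, `conf.high`,
#'   `ci_method`.
#' @export
auroc <- function(scores, labels, ci_method = c("delong", "hanley")) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    abort("Both classes must be present.", class = "neohrv_invalid_spec")
  }
  roc <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                   quiet = TRUE)
  a <- as.numeric(pROC::auc(roc))
  if (ci_method == "delong") {
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong")))
    lo <- ci[1]; hi <- ci[3]
  } else {
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                  (n0 - 1) * (q2 - a^2)) / (n1 * n0))
    lo <- max(0, a - 1.96 * se); hi <- min(1, a + 1.96 * se)
  }
  tibble::tibble(auroc = a, conf.low = lo, conf.high = hi,
                 ci_method = ci_method)
}

#' Youden-optimal operating point
#'
#' Scans all observed score values as cutoffs (predicted positive when
#' `score >= cutoff`) and returns the cutoff maximizing Youden's index
#' `sensitivity + specificity - 1`; ties are broken towards the higher
#' specificity. Sensitivity, specificity, PPV and NPV are reported at
#' that cutoff.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1); both classes must be present.
#'
#' @return A one-row tibble: `cutoff`, `youden`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    abort("Both classes must be present.", class = "neohrv_invalid_spec")
  }
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stats_at <- function(cut) {
    pos <- scores >= cut
    tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
    sens <- tp / n1
    spec <- (n0 - fp) / n0
    c(sens = sens, spec = spec, tp = tp, fp = fp)
  }
  grid <- t(vapply(cand, stats_at, numeric(4)))
  j <- grid[, "sens"] + grid[, "spec"] - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(grid[best, "spec"])]
  s <- grid[pick, ]
  tn <- n0 - s[["fp"]]; fn <- n1 - s[["tp"]]
  tibble::tibble(
    cutoff = cand[pick], youden = j[pick],
    sensitivity = s[["sens"]], specificity = s[["spec"]],
    ppv = if (s[["tp"]] + s[["fp"]] > 0) s[["tp"]] / (s[["tp"]] + s[["fp"]])
          else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping of the predicted probabilities, with the
#' usual chi-squared statistic `sum((O - E)^2 / (E (1 - E/n_g)))` over
#' groups referred to a chi-squared distribution on `g - 2` degrees of
#' freedom. Tied probability quantiles cause groups to be merged (with a
#' warning); `p < 0.05` indicates lack of fit.
#'
#' @param probs Predicted probabilities from a fitted model.
#' @param labels Binary outcomes (0/1).
#' @param g Number of risk groups (default 10; must leave positive
#'   degrees of freedom).
#'
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `g`.
#' @export
hosmer_lemeshow <- function(probs, labels, g = 10) {
  labels <- as.integer(labels)
  n <- length(probs)
  if (g <= 2) {
    abort("`g` must exceed 2 to leave positive degrees of freedom.",
          class = "neohrv_invalid_spec")
  }
  if (n < 2 * g) {
    abort("Need at least 2 observations per risk group.",
          class = "neohrv_insufficient_data")
  }
  brks <- quantile(probs, seq(0, 1, length.out = g + 1), type = 2)
  brks <- unique(brks)
  if (length(brks) - 1 < g) {
    warn(sprintf("Tied probabilities: merged to %d risk groups.",
                 length(brks) - 1), class = "neohrv_merged_groups")
  }
  if (length(brks) < 2) {
    # all probabilities identical: a single group carries no lack-of-fit
    # information; report a zero statistic on 1 df
    o <- sum(labels); e <- sum(probs)
    stat <- (o - e)^2 / max(e * (1 - e / n), .Machine$double.eps)
    return(tibble::tibble(statistic = stat, df = 1, p.value = pchisq(
      stat, 1, lower.tail = FALSE), g = 1))
  }
  grp <- cut(probs, breaks = brks, include.lowest = TRUE)
  o <- tapply(labels, grp, sum)
  e <- tapply(probs, grp, sum)
  ng <- tapply(rep(1, n), grp, sum)
  keep <- !is.na(o)
  o <- o[keep]; e <- e[keep]; ng <- ng[keep]
  denom <- e * (1 - e / ng)
  if (any(denom <= 0)) {
    warn("Degenerate expected counts: affected groups dropped.",
         class = "neohrv_merged_groups")
    ok <- denom > 0
    o <- o[ok]; e <- e[ok]; ng <- ng[ok]; denom <- denom[ok]
  }
  gg <- length(o)
  stat <- sum((o - e)^2 / denom)
  df <- max(gg - 2, 1)
  tibble::tibble(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE), g = gg)
}

#' Full evaluation of a risk model's scores
#'
#' Combines [auroc()], [youden_cutoff()] and [hosmer_lemeshow()] into the
#' standard evaluation row reported for each prediction model.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary outcomes (0/1).
#' @param g Hosmer-Lemeshow group count.
#' @param ci_method Passed to [auroc()].
#'
#' @return A one-row tibble with AUROC + CI, the Youden operating point
#'   (cutoff, sensitivity, specificity, PPV, NPV), the Hosmer-Lemeshow
#'   statistic/df/p and `n`.
#' @export
evaluate_model <- function(probs, labels, g = 10,
                           ci_method = c("delong", "hanley")) {
  a <- auroc(probs, labels, ci_method = ci_method)
  y <- youden_cutoff(probs, labels)
  h <- hosmer_lemeshow(probs, labels, g = g)
  tibble::tibble(
    auroc = a$auroc, auroc_low = a$conf.low, auroc_high = a$conf.high,
    cutoff = y$cutoff, sensitivity = y$sensitivity,
    specificity = y$specificity, ppv = y$ppv, npv = y$npv,
    hl_statistic = h$statistic, hl_df = h$df, hl_p = h$p.value,
    n = length(probs))
}
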