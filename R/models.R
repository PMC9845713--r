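#' Fit a multivariable logistic risk model
#'
#' Maximum-likelihood logistic regression of a binary EEG-grade outcome
#' (moderate-severe = 1) on the given terms, restricted to complete
#' cases. Binary covariates are expected encoded 0/1 and standardized
#' features pre-transformed (see [standardize_features()]). A warning is
#' raised when fitted probabilities collapse to 0/1, indicating
#' quasi-separation.
#'
#' @param data Data frame with the outcome and term columns.
#' @param outcome Name of the binary outcome column.
#' @param terms Character vector of predictor column names.
#' @param recipe Optional standardization recipe to store with the model
#'   for later application to raw features.
#'
#' @return An object of class `hie_model` with elements `intercept`,
#'   `terms` (tibble: `term`, `coefficient`, `transform`), `fit` (the
#'   underlying `glm`), `recipe`, `provenance = "fitted"`, `n_used` and
#'   `n_dropped`.
#' @export
fit_hie_model <- function(data, outcome, terms, recipe = NULL) {
  y <- data[[outcome]]
  if (is.null(y)) {
    abort(sprintf("Outcome column `%s` not found.", outcome),
          class = "neohrv_missing_term")
  }
  missing_terms <- setdiff(terms, names(data))
  if (length(missing_terms)) {
    abort(paste0("Missing model terms: ",
                 paste(missing_terms, collapse = ", ")),
          class = "neohrv_missing_term")
  }
  cc <- complete.cases(data[, c(outcome, terms), drop = FALSE])
  dat <- data[cc, , drop = FALSE]
  yv <- dat[[outcome]]
  if (length(unique(yv)) < 2) {
    abort("Outcome is constant on the complete cases.",
          class = "neohrv_degenerate_outcome")
  }
  separated <- FALSE
  fml <- if (length(terms)) reformulate(terms, response = outcome)
         else stats::as.formula(paste(outcome, "~ 1"))
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dat,
        control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated) {
    warn("Fitted probabilities of 0 or 1 occurred: possible quasi-separation.",
         class = "neohrv_separation")
  }
  cf <- coef(fit)
  structure(
    list(intercept = unname(cf[1]),
         terms = tibble::tibble(term = terms,
                                coefficient = unname(cf[-1][terms]),
                                transform = "identity",
                                printed_or = NA_real_),
         outcome = outcome, fit = fit, recipe = recipe,
         provenance = "fitted",
         n_used = nrow(dat), n_dropped = sum(!cc)),
    class = "hie_model"
  )
}

#' Univariable screening of candidate predictors
#'
#' Fits one single-predictor logistic regression per candidate (each on
#' its own complete cases), reporting the odds ratio with its Wald 95%
#' CI, the Wald p-value and the univariable AUROC of the fitted
#' probabilities. Candidates with p below `p_threshold` are flagged
#' eligible for multivariable modelling; among pairs of eligible
#' candidates whose absolute Pearson correlation exceeds
#' `cor_threshold`, only the one with the higher univariable AUROC is
#' kept.
#'
#' @param data Data frame with outcome and candidate columns.
#' @param outcome Name of the binary outcome column.
#' @param candidates Character vector of candidate predictor columns.
#' @param p_threshold Eligibility threshold on the univariable p-value
#'   (default 0.25).
#' @param cor_threshold Absolute-correlation threshold for pruning
#'   (default 0.8).
#'
#' @return A tibble of class `hie_screen`: `variable`, `n`, `estimate`,
#'   `std.error`, `or`, `conf.low`, `conf.high`, `p.value`, `auroc`,
#'   `eligible`, `kept`, `pruned_by`.
#' @export
univariable_screen <- function(data, outcome, candidates,
                               p_threshold = 0.25, cor_threshold = 0.8) {
  if (!length(candidates)) {
    abort("At least one candidate is required.",
          class = "neohrv_invalid_spec")
  }
  res <- purrr::map_dfr(candidates, function(v) {
    d <- data[complete.cases(data[, c(outcome, v)]), c(outcome, v)]
    fit <- suppressWarnings(
      glm(reformulate(v, outcome), family = binomial(), data = d))
    sm <- summary(fit)$coefficients
    b <- sm[2, 1]; se <- sm[2, 2]; p <- sm[2, 4]
    a <- suppressWarnings(as.numeric(pROC::auc(
      pROC::roc(d[[outcome]], stats::fitted(fit), levels = c(0, 1),
                direction = "<", quiet = TRUE))))
    tibble::tibble(variable = v, n = nrow(d), estimate = b,
                   std.error = se, or = exp(b),
                   conf.low = exp(b - 1.96 * se),
                   conf.high = exp(b + 1.96 * se),
                   p.value = p, auroc = a)
  })
  res$eligible <- res$p.value < p_threshold
  # greedy pruning in decreasing AUROC order among eligible candidates
  res$kept <- res$eligible
  res$pruned_by <- NA_character_
  elig <- res$variable[res$eligible]
  if (length(elig) > 1) {
    cm <- suppressWarnings(
      cor(data[, elig, drop = FALSE], use = "pairwise.complete.obs"))
    ord <- elig[order(-res$auroc[match(elig, res$variable)])]
    kept <- character(0)
    for (v in ord) {
      clash <- kept[!is.na(cm[v, kept]) & abs(cm[v, kept]) > cor_threshold]
      if (length(clash)) {
        res$kept[res$variable == v] <- FALSE
        res$pruned_by[res$variable == v] <- clash[1]
      } else {
        kept <- c(kept, v)
      }
    }
  }
  class(res) <- c("hie_screen", class(res))
  res
}

published_coefs <- list(
  hrv = list(
    intercept = 0.49,
    term = c("mean_nn_ms", "hf_power_ms2", "lf_hf_ratio", "tinn_ms",
             "mse_complexity_index", "mse_short_slope"),
    coefficient = c(1.00, 0.37, 0.40, -0.50, -0.51, -1.16),
    transform = c("standardized", "log10_standardized", "log10_standardized",
                  "log10_standardized", "standardized", "standardized"),
    printed_or = c(2.73, 1.45, 1.48, 0.61, 0.60, 0.31)
  ),
  clinical = list(
    intercept = 9.71,
    term = c("foetal_distress", "ga_weeks", "emergency_delivery", "apgar5",
             "ventilation_10min"),
    coefficient = c(-1.26, -0.25, -0.32, -0.07, 2.70),
    transform = rep("identity", 5),
    printed_or = c(0.28, 0.78, 0.73, 0.93, 14.92)
  ),
  combined = list(
    intercept = 11.49,
    term = c("mean_nn_ms", "hf_power_ms2", "lf_hf_ratio", "tinn_ms",
             "mse_complexity_index", "mse_short_slope", "foetal_distress",
             "ga_weeks", "emergency_delivery", "apgar5", "ventilation_10min"),
    coefficient = c(0.85, 0.66, 0.42, -0.35, -0.18, -1.04, -1.20, -0.28,
                    -0.46, -0.06, 2.19),
    transform = c("standardized", "log10_standardized", "log10_standardized",
                  "log10_standardized", "standardized", "standardized",
                  rep("identity", 5)),
    printed_or = c(2.34, 1.94, 1.51, 0.70, 0.84, 0.35, 0.30, 0.76, 0.63,
                   0.94, 8.94)
  )
)

#' Published logistic prediction models
#'
#' Returns the three published multivariable equations (HRV-only,
#' clinical-only, and combined) with intercepts and coefficients exactly
#' as printed (two decimal places); derived quantities inherit that
#' rounding. HRV terms enter as standardized (optionally
#' log10-transformed) features; clinical flags are binary 0/1, gestational
#' age is in weeks and the 5-minute Apgar is an integer score.
#'
#' @param name One of `"hrv"`, `"clinical"`, `"combined"`.
#'
#' @return An object of class `hie_model` with
#'   `provenance = "transcribed"`.
#' @export
#' @examples
#' m <- published_model("hrv")
#' tidy(m)
published_model <- function(name = c("hrv", "clinical", "combined")) {
  name <- match.arg(name)
  p <- published_coefs[[name]]
  structure(
    list(intercept = p$intercept,
         terms = tibble::tibble(term = p$term, coefficient = p$coefficient,
                                transform = p$transform,
                                printed_or = p$printed_or),
         outcome = "eeg_grade_binary", fit = NULL, recipe = NULL,
         provenance = "transcribed", name = name,
         n_used = 101L, n_dropped = NA_integer_),
    class = "hie_model"
  )
}

#' Predicted probability of a moderate-severe EEG grade
#'
#' Applies a model's linear predictor to each row and returns
#' `1 / (1 + exp(-eta))`. For terms with a standardization transform, a
#' `recipe` (or the model's stored recipe) is applied to the raw feature
#' columns first; when no recipe is available the columns are assumed to
#' be standardized already.
#'
#' @param model An `hie_model`.
#' @param newdata Data frame with one row per subject.
#' @param recipe Optional [standardize_features()] recipe overriding the
#'   model's own.
#'
#' @return Numeric vector of probabilities.
#' @export
predict_risk <- function(model, newdata, recipe = NULL) {
  stopifnot(inherits(model, "hie_model"))
  recipe <- recipe %||% model$recipe
  std_terms <- model$terms$term[model$terms$transform != "identity"]
  if (!is.null(recipe) && length(std_terms)) {
    rec <- recipe[recipe$feature %in% std_terms, , drop = FALSE]
    newdata <- standardize_features(newdata, recipe = rec)$data
  }
  eta <- rep(model$intercept, nrow(newdata))
  for (k in seq_len(nrow(model$terms))) {
    v <- model$terms$term[k]
    if (!v %in% names(newdata)) {
      abort(sprintf("Model term `%s` is missing from `newdata`.", v),
            class = "neohrv_missing_term")
    }
    eta <- eta + model$terms$coefficient[k] * newdata[[v]]
  }
  plogis(eta)
}

#' @export
print.hie_model <- function(x, ...) {
  cat(sprintf("<hie_model> %s (%s), %d terms, n = %s\n",
              x$name %||% x$outcome, x$provenance, nrow(x$terms),
              x$n_used %||% NA))
  print(tidy(x))
  invisible(x)
}

#' Tidy an HRV/clinical risk model
#'
#' @param x An `hie_model`.
#' @param ... Unused.
#' @return A tibble with one row per term (including the intercept):
#'   `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `odds.ratio`, `conf.low`, `conf.high` (Wald, on the OR scale).
#'   Standard errors are `NA` for transcribed models.
#' @method tidy hie_model
#' @export
tidy.hie_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    sm <- summary(x$fit)$coefficients
    out <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                          std.error = sm[, 2], statistic = sm[, 3],
                          p.value = sm[, 4])
  } else {
    out <- tibble::tibble(
      term = c("(Intercept)", x$terms$term),
      estimate = c(x$intercept, x$terms$coefficient),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_)
  }
  out$odds.ratio <- exp(out$estimate)
  out$conf.low <- exp(out$estimate - 1.96 * out$std.error)
  out$conf.high <- exp(out$estimate + 1.96 * out$std.error)
  out$odds.ratio[out$term == "(Intercept)"] <- NA_real_
  out
}

#' Model-level summary of an `hie_model`
#'
#' @param x An `hie_model`.
#' @param ... Unused.
#' @return A one-row tibble: `provenance`, `n`, `n_terms`, and (for
#'   fitted models) `deviance`, `null.deviance`, `aic`.
#' @method glance hie_model
#' @export
glance.hie_model <- function(x, ...) {
  tibble::tibble(
    provenance = x$provenance, n = x$n_used %||% NA_integer_,
    n_terms = nrow(x$terms),
    deviance = if (!is.null(x$fit)) x$fit$deviance else NA_real_,
    null.deviance = if (!is.null(x$fit)) x$fit$null.deviance else NA_real_,
    aic = if (!is.null(x$fit)) x$fit$aic else NA_real_)
}

#' Serialize a model to JSON / read it back
#'
#' The structured text representation stores the intercept, term table,
#' standardization recipe, outcome and provenance, so a fitted or
#' transcribed model round-trips through disk and [predict_risk()]
#' exactly.
#'
#' @param model An `hie_model`.
#' @param path File path for the JSON document.
#' @return `write_hie_model()` returns `path` invisibly;
#'   `read_hie_model()` returns an `hie_model`.
#' @export
write_hie_model <- function(model, path) {
  stopifnot(inherits(model, "hie_model"))
  obj <- list(intercept = model$intercept,
              terms = model$terms,
              outcome = model$outcome,
              provenance = model$provenance,
              name = model$name %||% NULL,
              n_used = model$n_used,
              recipe = model$recipe)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_hie_model
#' @export
read_hie_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(intercept = obj$intercept,
         terms = tibble::as_tibble(obj$terms),
         outcome = obj$outcome, fit = NULL,
         recipe = if (is.null(obj$recipe)) NULL
                  else tibble::as_tibble(obj$recipe),
         provenance = obj$provenance, name = obj$name,
         n_used = obj$n_used, n_dropped = NA_integer_),
    class = "hie_model"
  )
}
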