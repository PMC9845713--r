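#' Configuration of the modelling stage
#'
#' @param p_threshold Univariable eligibility threshold (default 0.25).
#' @param cor_threshold Correlation-pruning threshold (default 0.8).
#' @param hl_groups Hosmer-Lemeshow risk groups (default 10).
#' @param subgroup `"none"` (default), `"cooled"` (therapeutic-hypothermia
#'   subgroup) or `"no_asm"` (no anti-seizure medication before the
#'   epoch).
#' @param include_gases Also screen cord pH, lactate and base deficit
#'   (used for the subgroup analyses; excluded from the main analysis
#'   because of missingness).
#' @param ci_method AUROC CI method, `"delong"` or `"hanley"`.
#'
#' @return A list of class `study_config`.
#' @export
study_config <- function(p_threshold = 0.25, cor_threshold = 0.8,
                         hl_groups = 10,
                         subgroup = c("none", "cooled", "no_asm"),
                         include_gases = FALSE,
                         ci_method = c("delong", "hanley")) {
  if (p_threshold <= 0 || p_threshold > 1 ||
      cor_threshold <= 0 || cor_threshold > 1) {
    abort("Thresholds must lie in (0, 1].", class = "neohrv_invalid_spec")
  }
  structure(list(p_threshold = p_threshold, cor_threshold = cor_threshold,
                 hl_groups = hl_groups, subgroup = match.arg(subgroup),
                 include_gases = include_gases,
                 ci_method = match.arg(ci_method)),
            class = "study_config")
}

# clinical candidates with the units used for their odds ratios:
# birth weight per 100 g, cord pH per 0.01
clinical_candidates <- function(include_gases = FALSE) {
  base <- c("intrapartum_complications", "foetal_distress", "ga_weeks",
            "emergency_delivery", "male", "bw_100g", "apgar1", "apgar5",
            "ventilation_10min")
  if (include_gases) c(base, "ph_centi", "lactate", "base_deficit") else base
}

#' Run the full screening + modelling + evaluation study
#'
#' Reproduces the analysis pipeline on a feature table and clinical
#' table: HRV features are log10-transformed where skewed and
#' standardized, all HRV and clinical candidates are screened
#' univariably, eligible uncorrelated variables feed three multivariable
#' logistic models (HRV-only, clinical-only, combined), fitted on the
#' complete-case subset shared by all model terms, and each model is
#' evaluated by AUROC with CI, the Youden operating point and the
#' Hosmer-Lemeshow test.
#'
#' @param features Feature table from [extract_features()] (columns
#'   `subject_id` plus [hrv_feature_names()]).
#' @param clinical Clinical table (see [simulate_clinical()] for the
#'   expected columns), including the binary `group` outcome.
#' @param config A [study_config()].
#'
#' @return An object of class `hie_study`: `screen` (combined screening
#'   tibble with a `family` column), `models` (named list of three
#'   `hie_model`s), `evaluations` (tibble, one row per model), `recipe`,
#'   `n_total`, `n_complete` and `config`.
#' @export
run_study <- function(features, clinical, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  dat <- dplyr::inner_join(clinical,
                           dplyr::select(features, -dplyr::any_of("group")),
                           by = "subject_id")
  dat <- switch(config$subgroup,
    none = dat,
    cooled = dat[!is.na(dat$cooled) & dat$cooled == 1, ],
    no_asm = dat[!is.na(dat$asm_before_epoch) & dat$asm_before_epoch == 0, ])
  if (!nrow(dat)) {
    abort("No subjects left after subgroup filtering.",
          class = "neohrv_insufficient_data")
  }
  dat$bw_100g <- dat$bw_g / 100
  if ("ph" %in% names(dat)) dat$ph_centi <- dat$ph * 100
  hrv_vars <- intersect(hrv_feature_names(), names(dat))
  # features that were not computed (e.g. entropy disabled) or are
  # degenerate on this cohort cannot be standardized or screened
  usable <- vapply(hrv_vars, function(v) {
    x <- dat[[v]]
    sum(!is.na(x)) >= 3 && isTRUE(sd(x, na.rm = TRUE) > 0)
  }, logical(1))
  hrv_vars <- hrv_vars[usable]
  if (!length(hrv_vars)) {
    abort("No usable HRV feature columns found.",
          class = "neohrv_insufficient_data")
  }
  std <- standardize_features(dat, cols = hrv_vars)
  dat <- std$data
  clin_vars <- intersect(clinical_candidates(config$include_gases),
                         names(dat))
  screen_hrv <- univariable_screen(dat, "group", hrv_vars,
                                   p_threshold = config$p_threshold,
                                   cor_threshold = config$cor_threshold)
  screen_clin <- univariable_screen(dat, "group", clin_vars,
                                    p_threshold = config$p_threshold,
                                    cor_threshold = config$cor_threshold)
  screen <- dplyr::bind_rows(
    dplyr::mutate(screen_hrv, family = "hrv"),
    dplyr::mutate(screen_clin, family = "clinical"))
  hrv_terms <- screen_hrv$variable[screen_hrv$kept]
  clin_terms <- screen_clin$variable[screen_clin$kept]
  all_terms <- union(hrv_terms, clin_terms)
  cc <- complete.cases(dat[, c("group", all_terms), drop = FALSE])
  cdat <- dat[cc, , drop = FALSE]
  fit_one <- function(terms) {
    fit_hie_model(cdat, "group", terms, recipe = std$recipe)
  }
  models <- list(hrv = fit_one(hrv_terms),
                 clinical = fit_one(clin_terms),
                 combined = fit_one(all_terms))
  evaluations <- purrr::map_dfr(names(models), function(nm) {
    m <- models[[nm]]
    probs <- if (nrow(m$terms)) stats::fitted(m$fit)
             else rep(mean(cdat$group), nrow(cdat))
    dplyr::bind_cols(
      tibble::tibble(model = nm),
      evaluate_model(probs, cdat$group, g = config$hl_groups,
                     ci_method = config$ci_method))
  })
  structure(
    list(screen = screen, models = models, evaluations = evaluations,
         recipe = std$recipe, n_total = nrow(dat), n_complete = nrow(cdat),
         config = config),
    class = "hie_study"
  )
}

#' @export
print.hie_study <- function(x, ...) {
  cat(sprintf("<hie_study> %d subjects (%d complete cases), subgroup: %s\n",
              x$n_total, x$n_complete, x$config$subgroup))
  cat("Model terms:\n")
  for (nm in names(x$models)) {
    cat(sprintf("  %-9s %s\n", nm,
                paste(x$models[[nm]]$terms$term, collapse = ", ")))
  }
  cat("Evaluations:\n")
  print(x$evaluations)
  invisible(x)
}

#' Tidy a study: per-term coefficients of all three models
#'
#' @param x An `hie_study`.
#' @param ... Unused.
#' @return A tibble of [tidy.hie_model()] rows with a `model` column.
#' @method tidy hie_study
#' @export
tidy.hie_study <- function(x, ...) {
  purrr::map_dfr(names(x$models),
                 function(nm) dplyr::mutate(tidy(x$models[[nm]]),
                                            model = nm, .before = 1))
}

#' Study-level summary: one evaluation row per model
#'
#' @param x An `hie_study`.
#' @param ... Unused.
#' @return The `evaluations` tibble with cohort sizes attached.
#' @method glance hie_study
#' @export
glance.hie_study <- function(x, ...) {
  dplyr::mutate(x$evaluations, n_total = x$n_total,
                n_complete = x$n_complete)
}
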