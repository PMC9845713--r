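#' Read a pipeline run configuration
#'
#' The run configuration is a single YAML document with optional blocks
#' `simulate` (n_per_group, epoch_duration_s, profile overrides),
#' `extract` (band preset, mse settings, artifact thresholds), `model`
#' ([study_config()] fields), `input` and `model_path`. All thresholds
#' are surfaced here; there are no hidden constants.
#'
#' @param config A YAML file path, or a list already in memory.
#' @return The configuration list, validated and with defaults filled in.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("Config file `%s` not found.", config),
            class = "neohrv_invalid_spec")
    }
    config <- yaml::read_yaml(config)
  }
  config$simulate <- config$simulate %||% list()
  config$extract <- config$extract %||% list()
  config$model <- config$model %||% list()
  config
}

# every command writes a provenance block: config hash, seed and package
# version make deterministic stages reproducible bit for bit
write_provenance <- function(out_dir, config, seed) {
  prov <- list(config_hash = rlang::hash(config),
               seed = seed,
               package = "neohrv",
               version = as.character(utils::packageVersion("neohrv")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(prov)
}

extract_config_from <- function(cfg) {
  ex <- cfg$extract
  bands <- spectral_bands(preset = ex$band_preset %||% "neonatal",
                          resample_hz = ex$resample_hz %||% 4)
  mse <- if (isFALSE(ex$mse)) NULL else {
    mse_config(m = ex$mse_m %||% 2, r_factor = ex$mse_r_factor %||% 0.15,
               scales = seq_len(ex$mse_max_scale %||% 20))
  }
  list(bands = bands, mse = mse,
       min_ms = ex$artifact_min_ms %||% 200,
       max_ms = ex$artifact_max_ms %||% 1200,
       rel_dev = ex$artifact_rel_dev %||% 0.3)
}

study_config_from <- function(cfg) {
  m <- cfg$model
  study_config(p_threshold = m$p_threshold %||% 0.25,
               cor_threshold = m$cor_threshold %||% 0.8,
               hl_groups = m$hl_groups %||% 10,
               subgroup = m$subgroup %||% "none",
               include_gases = m$include_gases %||% FALSE,
               ci_method = m$ci_method %||% "delong")
}

#' Pipeline commands
#'
#' Thin wrappers tying the stages into reproducible disk-to-disk runs;
#' each writes its outputs plus a provenance block (config hash, seed,
#' package version) under `out`. They are also exposed through the
#' `inst/cli/neohrv` command-line dispatcher with subcommands
#' `simulate | extract | fit | evaluate | predict`.
#'
#' * `cmd_simulate()` generates a synthetic cohort
#'   (`clinical.tsv` + `rr/` tables).
#' * `cmd_extract()` reads a cohort directory, applies artifact rules and
#'   segmentation, and writes `features.tsv`.
#' * `cmd_fit()` runs the full study and writes the screening table,
#'   the three model JSON files and `evaluations.tsv`.
#' * `cmd_evaluate()` re-evaluates a serialized model on a feature +
#'   clinical table.
#' * `cmd_predict()` writes per-subject predicted probabilities from a
#'   serialized model.
#'
#' @param config YAML path or config list (see [read_run_config()]).
#' @param seed Integer seed for the stochastic stages.
#' @param out Output directory (created if needed).
#' @return The principal result of the stage, invisibly (cohort, feature
#'   table, `hie_study`, evaluation tibble, or prediction tibble).
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(config = list(), seed = 1L, out) {
  cfg <- read_run_config(config)
  sim <- cfg$simulate
  profiles <- default_group_profiles()
  for (grp in c("mild", "severe")) {
    ov <- sim[[paste0(grp, "_profile")]]
    if (!is.null(ov)) {
      profiles[[grp]] <- do.call(group_profile, utils::modifyList(
        unclass(profiles[[grp]]), ov))
    }
  }
  spec <- cohort_spec(n_per_group = sim$n_per_group %||% 50,
                      group_profiles = profiles,
                      epoch_duration_s = sim$epoch_duration_s %||% 3600,
                      seed = seed)
  cohort <- simulate_cohort(spec)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, out)
  write_provenance(out, cfg, seed)
  invisible(cohort)
}

#' @rdname pipeline-commands
#' @export
cmd_extract <- function(config = list(), seed = 1L, out) {
  cfg <- read_run_config(config)
  input <- cfg$input %||% abort("`input` cohort directory is required.",
                                class = "neohrv_invalid_spec")
  cohort <- read_cohort(input)
  ex <- extract_config_from(cfg)
  feats <- extract_features(cohort, bands = ex$bands, mse = ex$mse,
                            min_ms = ex$min_ms, max_ms = ex$max_ms,
                            rel_dev = ex$rel_dev)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(feats, file.path(out, "features.tsv"))
  write_provenance(out, cfg, seed)
  invisible(feats)
}

read_fit_inputs <- function(cfg) {
  feats <- readr::read_tsv(cfg$features %||%
                             abort("`features` path required.",
                                   class = "neohrv_invalid_spec"),
                           show_col_types = FALSE)
  clin <- readr::read_tsv(cfg$clinical %||%
                            abort("`clinical` path required.",
                                  class = "neohrv_invalid_spec"),
                          show_col_types = FALSE)
  list(features = feats, clinical = clin)
}

#' @rdname pipeline-commands
#' @export
cmd_fit <- function(config = list(), seed = 1L, out) {
  cfg <- read_run_config(config)
  inp <- read_fit_inputs(cfg)
  study <- run_study(inp$features, inp$clinical, study_config_from(cfg))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$screen, file.path(out, "screen.tsv"))
  readr::write_tsv(study$evaluations, file.path(out, "evaluations.tsv"))
  for (nm in names(study$models)) {
    write_hie_model(study$models[[nm]],
                    file.path(out, sprintf("model_%s.json", nm)))
  }
  summary_lines <- utils::capture.output(print(study))
  writeLines(summary_lines, file.path(out, "summary.txt"))
  write_provenance(out, cfg, seed)
  invisible(study)
}

#' @rdname pipeline-commands
#' @export
cmd_evaluate <- function(config = list(), seed = 1L, out) {
  cfg <- read_run_config(config)
  inp <- read_fit_inputs(cfg)
  model <- read_hie_model(cfg$model_path %||%
                            abort("`model_path` required.",
                                  class = "neohrv_invalid_spec"))
  dat <- dplyr::inner_join(inp$clinical,
                           dplyr::select(inp$features,
                                         -dplyr::any_of("group")),
                           by = "subject_id")
  dat <- dat[complete.cases(dat[, c("group", model$terms$term)]), ]
  probs <- predict_risk(model, dat)
  ev <- evaluate_model(probs, dat$group,
                       g = cfg$model$hl_groups %||% 10)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(ev, file.path(out, "evaluation.tsv"))
  write_provenance(out, cfg, seed)
  invisible(ev)
}

#' @rdname pipeline-commands
#' @export
cmd_predict <- function(config = list(), seed = 1L, out) {
  cfg <- read_run_config(config)
  inp <- read_fit_inputs(cfg)
  model <- read_hie_model(cfg$model_path %||%
                            abort("`model_path` required.",
                                  class = "neohrv_invalid_spec"))
  dat <- dplyr::inner_join(inp$clinical,
                           dplyr::select(inp$features,
                                         -dplyr::any_of("group")),
                           by = "subject_id")
  pred <- tibble::tibble(subject_id = dat$subject_id,
                         risk = predict_risk(model, dat))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(pred, file.path(out, "predictions.tsv"))
  write_provenance(out, cfg, seed)
  invisible(pred)
}
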