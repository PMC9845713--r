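#' Read and write RR-interval series as plain text
#'
#' The on-disk format is a two-column whitespace/tab-delimited table of
#' beat time (s) and preceding interval (ms), with an optional third
#' 0/1 artifact column; a `#` header line records the postnatal start
#' age.
#'
#' @param rr An `rr_series` tibble.
#' @param path File path.
#' @return `write_rr()` returns `path` invisibly; `read_rr()` returns an
#'   `rr_series` tibble.
#' @export
write_rr <- function(rr, path) {
  check_rr(rr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# start_age_h=%.6f", attr(rr, "start_age_h") %||% 0),
             con)
  writeLines("time_s\tinterval_ms\tartifact", con)
  writeLines(sprintf("%.6f\t%.6f\t%d", rr$time_s, rr$interval_ms,
                     as.integer(rr$artifact)), con)
  invisible(path)
}

#' @rdname write_rr
#' @export
read_rr <- function(path) {
  first <- readLines(path, n = 1)
  age <- if (startsWith(first, "#")) {
    as.numeric(sub(".*start_age_h=", "", first))
  } else 0
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!"artifact" %in% names(tab)) tab$artifact <- 0L
  new_rr_series(tab$time_s, tab$interval_ms, as.logical(tab$artifact),
                start_age_h = age)
}

#' Write/read a cohort directory
#'
#' A cohort is stored as `clinical.tsv` (one row per subject) plus an
#' `rr/` directory of per-subject two-column RR tables named by subject
#' identifier.
#'
#' @param cohort Cohort tibble with an `rr` list-column, as from
#'   [simulate_cohort()].
#' @param dir Directory to create/read.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns the cohort tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "rr"), recursive = TRUE, showWarnings = FALSE)
  clin <- dplyr::select(cohort, -dplyr::any_of("rr"))
  readr::write_tsv(clin, file.path(dir, "clinical.tsv"))
  purrr::walk2(cohort$rr, cohort$subject_id, function(rr, id) {
    write_rr(rr, file.path(dir, "rr", paste0(id, ".tsv")))
  })
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  clin <- readr::read_tsv(file.path(dir, "clinical.tsv"),
                          show_col_types = FALSE)
  clin$rr <- purrr::map(clin$subject_id, function(id) {
    read_rr(file.path(dir, "rr", paste0(id, ".tsv")))
  })
  clin
}

#' Read a plain-text single-channel ECG
#'
#' One numeric sample per line (comment lines starting with `#`
#' ignored); the sampling rate is supplied by the caller.
#'
#' @param path File path.
#' @return Numeric vector of samples.
#' @export
read_ecg <- function(path) {
  lines <- readLines(path)
  as.numeric(lines[!startsWith(lines, "#")])
}
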