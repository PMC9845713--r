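#' Standardize HRV features, optionally after a log10 transform
#'
#' Positively skewed features are log10-transformed and every feature is
#' then z-scored so regression coefficients are comparable (odds ratios
#' per one SD). When `recipe` is `NULL` a new recipe (per-feature
#' transform tag, mean and SD) is fitted on the data; a stored recipe can
#' be re-applied to new data, reproducing the fitted standardization
#' exactly.
#'
#' @param data Data frame containing the feature columns.
#' @param cols Columns to standardize (default: the [hrv_feature_names()]
#'   present in `data`).
#' @param log10_cols Columns to log10-transform first (default
#'   [hrv_log10_features()]); must be strictly positive.
#' @param recipe A recipe tibble from a previous call, or `NULL` to fit.
#'
#' @return A list with `data` (the input with standardized columns) and
#'   `recipe` (tibble with `feature`, `transform`, `mean`, `sd`).
#' @export
#' @examples
#' standardize_features(data.frame(mean_nn_ms = c(1, 2, 3)))$data
standardize_features <- function(data, cols = NULL, log10_cols = NULL,
                                 recipe = NULL) {
  if (is.null(recipe)) {
    cols <- cols %||% intersect(hrv_feature_names(), names(data))
    log10_cols <- log10_cols %||% intersect(hrv_log10_features(), cols)
    recipe <- purrr::map_dfr(cols, function(v) {
      x <- data[[v]]
      tr <- if (v %in% log10_cols) "log10" else "identity"
      if (tr == "log10") {
        if (any(x <= 0, na.rm = TRUE)) {
          abort(sprintf("Feature `%s` must be strictly positive for log10.", v),
                class = "neohrv_transform_error")
        }
        x <- log10(x)
      }
      s <- sd(x, na.rm = TRUE)
      if (!is.finite(s) || s <= 0) {
        abort(sprintf("Feature `%s` has zero variance; cannot standardize.", v),
              class = "neohrv_transform_error")
      }
      tibble::tibble(feature = v, transform = tr,
                     mean = mean(x, na.rm = TRUE), sd = s)
    })
  }
  for (k in seq_len(nrow(recipe))) {
    v <- recipe$feature[k]
    if (!v %in% names(data)) {
      abort(sprintf("Column `%s` required by the recipe is missing.", v),
            class = "neohrv_missing_term")
    }
    x <- data[[v]]
    if (recipe$transform[k] == "log10") {
      if (any(x <= 0, na.rm = TRUE)) {
        abort(sprintf("Feature `%s` must be strictly positive for log10.", v),
              class = "neohrv_transform_error")
      }
      x <- log10(x)
    }
    data[[v]] <- (x - recipe$mean[k]) / recipe$sd[k]
  }
  list(data = data, recipe = recipe)
}
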