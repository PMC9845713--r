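#' Plot a tachogram with artifact flags
#'
#' @param object An `rr_series` tibble.
#' @param ... Unused.
#' @return A ggplot of interval (ms) against beat time, flagged beats
#'   highlighted.
#' @method autoplot rr_series
#' @export
autoplot.rr_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$interval_ms)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(data = object[object$artifact, ],
                        colour = "firebrick", size = 1) +
    ggplot2::labs(x = "Time (s)", y = "NN interval (ms)",
                  title = "Tachogram (flagged beats in red)") +
    ggplot2::theme_minimal()
}

#' Plot a multiscale-entropy curve
#'
#' @param object An `mse_curve` tibble.
#' @param ... Unused.
#' @return A ggplot of entropy against scale factor.
#' @method autoplot mse_curve
#' @export
autoplot.mse_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scale, y = .data$entropy)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Scale factor", y = "Sample entropy (nats)",
                  title = "Multiscale entropy") +
    ggplot2::theme_minimal()
}

#' ROC curves of the three study models
#'
#' Recomputes each fitted model's ROC curve on the study's complete-case
#' cohort and overlays the three with their AUROCs in the legend.
#'
#' @param object An `hie_study` from [run_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hie_study
#' @export
autoplot.hie_study <- function(object, ...) {
  pts <- purrr::map_dfr(names(object$models), function(nm) {
    m <- object$models[[nm]]
    if (is.null(m$fit) || !nrow(m$terms)) return(NULL)
    probs <- stats::fitted(m$fit)
    labels <- m$fit$y
    roc <- pROC::roc(labels, probs, levels = c(0, 1), direction = "<",
                     quiet = TRUE)
    a <- object$evaluations$auroc[object$evaluations$model == nm]
    tibble::tibble(model = sprintf("%s (AUROC %.3f)", nm, a),
                   fpr = 1 - roc$specificities, tpr = roc$sensitivities)
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = NULL, title = "Risk-model ROC curves") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
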