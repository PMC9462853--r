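#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_col facet_wrap labs theme_minimal position_dodge geom_errorbar
#' @export
ggplot2::autoplot

#' Plot the block-reversal performance curve
#'
#' @param curve Output of [performance_curve()].
#' @return A ggplot: fraction of correct choices against trials since
#'   the last reward reversal.
#' @export
plot_performance_curve <- function(curve) {
  ggplot(curve, aes(x = .data$trials_since_reversal,
                    y = .data$p_correct)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    geom_line() +
    geom_point() +
    labs(x = "Trials since reward reversal", y = "P(correct choice)") +
    theme_minimal()
}

#' Plot trial-history regression weights
#'
#' @param object A `history_fit` or `inactivation_fit`.
#' @param ... Unused.
#' @return A ggplot of the lagged weights per outcome type (faceted by
#'   inactivation condition when present).
#' @export
autoplot.history_fit <- function(object, ...) {
  w <- tidy(object)
  p <- ggplot(w, aes(x = .data$lag, y = .data$estimate,
                     colour = .data$predictor)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line() +
    geom_point() +
    labs(x = "Lag (trials back)", y = "Regression weight",
         colour = "Outcome type") +
    theme_minimal()
  if ("condition" %in% names(w)) p <- p + facet_wrap(~condition)
  p
}

#' @rdname autoplot.history_fit
#' @export
autoplot.inactivation_fit <- autoplot.history_fit

#' Plot lagged planning indices by inactivation condition
#'
#' @param object A `planning_contrast`.
#' @param ... Unused.
#' @return A ggplot of the per-lag planning index (mean over rats) per
#'   condition.
#' @export
autoplot.planning_contrast <- function(object, ...) {
  d <- object$lagged |>
    dplyr::group_by(.data$condition, .data$lag) |>
    dplyr::summarise(mean = mean(.data$planning),
                     se = sd(.data$planning) /
                       sqrt(dplyr::n()), .groups = "drop")
  ggplot(d, aes(x = .data$lag, y = .data$mean,
                colour = .data$condition)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se),
                  width = 0.1, position = position_dodge(0.2)) +
    geom_point(position = position_dodge(0.2)) +
    geom_line(position = position_dodge(0.2)) +
    labs(x = "Lag (trials back)", y = "Planning index contribution",
         colour = "Condition") +
    theme_minimal()
}

#' Plot a CPD result
#'
#' For `population_bin` or `unit_bin` scope, a null-subtracted CPD
#' timecourse per regressor faceted by event; for `unit_event` scope, a
#' per-regressor summary of unit CPDs by event.
#'
#' @param object A `cpd_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpd_result <- function(object, ...) {
  scope <- attr(object, "scope")
  yvar <- if ("cpd_null_subtracted" %in% names(object)) {
    "cpd_null_subtracted"
  } else "cpd"
  if (scope %in% c("population_bin", "unit_bin")) {
    d <- object |>
      dplyr::group_by(.data$event, .data$bin, .data$regressor) |>
      dplyr::summarise(cpd = mean(.data[[yvar]], na.rm = TRUE),
                       .groups = "drop")
    ggplot(d, aes(x = .data$bin, y = 100 * .data$cpd,
                  colour = .data$regressor)) +
      geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
      geom_line() +
      facet_wrap(~event, nrow = 1) +
      labs(x = "Time bin", y = "CPD (%)", colour = "Regressor") +
      theme_minimal()
  } else {
    d <- object |>
      dplyr::group_by(.data$event, .data$regressor) |>
      dplyr::summarise(cpd = mean(.data[[yvar]], na.rm = TRUE),
                       .groups = "drop")
    ggplot(d, aes(x = .data$regressor, y = 100 * .data$cpd)) +
      geom_col() +
      facet_wrap(~event, nrow = 1) +
      labs(x = NULL, y = "Mean CPD (%)") +
      theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
}
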