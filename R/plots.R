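#' Plot a spline risk curve
#'
#' Fitted probability of the outcome against the z-score with its
#' pointwise confidence band; a U-shaped association shows as an interior
#' minimum.
#'
#' @param object A [spline_risk_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pv_spline_curve
#' @export
autoplot.pv_spline_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$prob)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "age-adjusted z-score",
                  y = "probability of major trauma") +
    ggplot2::theme_minimal()
}

#' Plot a calibration table
#'
#' Observed outcome rate against mean predicted probability per
#' equal-frequency bin, with the identity line.
#'
#' @param object A [calibration_bins()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pv_calibration
#' @export
autoplot.pv_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_pred,
                                       y = .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "mean predicted probability", y = "observed rate",
                  size = "n") +
    ggplot2::theme_minimal()
}

#' Plot a rule set's limits against age
#'
#' Step plot of the lower and upper limits per vital sign, one facet per
#' vital.
#'
#' @param object A `pv_ruleset`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pv_ruleset
#' @export
autoplot.pv_ruleset <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("lower", "upper"), names_to = "limit",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(colour = .data$limit)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$age_lo, xend = .data$age_hi,
                                       y = .data$value, yend = .data$value)) +
    ggplot2::facet_wrap(~vital, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "age (years)", y = "limit",
                  title = attr(object, "name")) +
    ggplot2::theme_minimal()
}
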