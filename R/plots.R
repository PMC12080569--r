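#' Plot a prediction-corrected visual predictive check
#'
#' Observed percentiles (lines with points) over the simulated percentile
#' medians and their confidence ribbons, by time bin.
#'
#' @param object A `pkpd_vpc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pkpd_vpc <- function(object, ...) {
  d <- object$stats
  d$percentile <- factor(paste0("p", d$percentile),
                         levels = c("p5", "p50", "p95"))
  ylab <- if (object$model == "pk") {
    "prediction-corrected concentration (ng/mL)"
  } else {
    "prediction-corrected HbA1c (%)"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_mid,
                                  group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi,
                                      fill = .data$percentile),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$simulated,
                                    colour = .data$percentile),
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$percentile)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$percentile)) +
    ggplot2::labs(x = "time after first dose (days)", y = ylab,
                  colour = "percentile", fill = "percentile") +
    ggplot2::theme_minimal()
}

#' Plot simulated dose-scenario HbA1c trajectories
#'
#' Median line with the 5th-95th percentile band over time; pass several
#' scenarios to overlay dose arms.
#'
#' @param object A `pkpd_scenario`.
#' @param ... Further `pkpd_scenario` objects to overlay.
#' @return A ggplot.
#' @export
autoplot.pkpd_scenario <- function(object, ...) {
  extra <- purrr::keep(list(...), inherits, "pkpd_scenario")
  all <- c(list(object), extra)
  d <- purrr::map_dfr(all, function(s) {
    dplyr::mutate(s$summary,
                  dose = if (is.infinite(s$dose_mg)) "maximal"
                         else paste0(s$dose_mg, " mg"))
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, group = .data$dose)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95,
                                      fill = .data$dose), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median,
                                    colour = .data$dose), linewidth = 1) +
    ggplot2::labs(x = "time after first dose (days)", y = "HbA1c (%)",
                  colour = "dose", fill = "dose") +
    ggplot2::theme_minimal()
}
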