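# ggplot2 visualisations for fitted objects and profiles.

#' Plot a Baranyi fit over its data
#'
#' @param object A `baranyi_fit`.
#' @param ... Unused.
#' @return A ggplot: observed log10 counts and the fitted growth curve.
#' @method autoplot baranyi_fit
#' @export
autoplot.baranyi_fit <- function(object, ...) {
  grid <- tibble(
    time_d = seq(0, max(object$data$time_d), length.out = 200L)
  )
  grid$log10_count <- baranyi_log_count(grid$time_d, object$params)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_d, .data$log10_count)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "Time (d)", y = "log10 CFU/g",
                  title = sprintf("Baranyi fit (R² = %.3f)",
                                  object$r_squared))
}

#' Plot a TTI logistic fit over its normalised readings
#'
#' @param object A `tti_logistic_fit`.
#' @param ... Unused.
#' @return A ggplot of the normalised response and fitted sigmoid.
#' @method autoplot tti_logistic_fit
#' @export
autoplot.tti_logistic_fit <- function(object, ...) {
  grid <- tibble(time_d = seq(0, max(object$data$time_d), length.out = 200L))
  grid$norm <- 1 / (1 + exp((object$k1 - grid$time_d) / object$k2))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_d, .data$norm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "darkorange") +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::labs(x = "Time (d)", y = "norm(a+b)",
                  title = "TTI logistic response (dashed: visual endpoint)")
}

#' Plot a temperature profile
#'
#' @param object A `temperature_profile`.
#' @param ... Unused.
#' @return A ggplot step plot of the time-temperature history.
#' @method autoplot temperature_profile
#' @export
autoplot.temperature_profile <- function(object, ...) {
  steps <- tibble(
    time_d = c(object$start_d, profile_duration(object)),
    temperature_C = c(object$temperature_C,
                      object$temperature_C[nrow(object)])
  )
  ggplot2::ggplot(steps, ggplot2::aes(.data$time_d, .data$temperature_C)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (d)", y = "Temperature (°C)")
}

#' Plot a shelf-life / TTI match report
#'
#' @param object A `tti_match` from [match_score()].
#' @param ... Unused.
#' @return A ggplot comparing shelf-life and label response over temperature.
#' @method autoplot tti_match
#' @export
autoplot.tti_match <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$table,
    c("shelf_life_d", "tti_response_d"),
    names_to = "curve", values_to = "days"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$temperature_C, .data$days,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$abuse_threshold_c,
                        linetype = "dotted") +
    ggplot2::scale_colour_discrete(
      labels = c(shelf_life_d = "Product shelf-life",
                 tti_response_d = "TTI response")) +
    ggplot2::labs(x = "Temperature (°C)", y = "Days", colour = NULL)
}
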