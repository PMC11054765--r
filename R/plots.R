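#' Plot a temperature log with detected wear intervals
#'
#' @param log Temperature tibble `(time, temp_c)`.
#' @param wear Interval tibble from [wear_intervals_from_temperature()];
#'   `NULL` computes it with defaults.
#' @return A ggplot.
#' @export
plot_wear_detection <- function(log, wear = NULL) {
  wear <- wear %||% wear_intervals_from_temperature(log)
  p <- ggplot2::ggplot(log, ggplot2::aes(x = .data$time, y = .data$temp_c))
  if (nrow(wear) > 0) {
    p <- p + ggplot2::geom_rect(
      data = wear,
      ggplot2::aes(xmin = .data$on, xmax = .data$off, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "In-device temperature (°C)",
                  title = "Device wear detected from the temperature log")
}

#' Plot the regional pressure curve of a trial with detected stances
#'
#' @param series A `pressure_frames` series.
#' @param mask A [region_mask()]; `NULL` uses the dialect's default
#'   ulcer-site mask.
#' @param force_threshold,min_duration Stance detection parameters.
#' @return A ggplot.
#' @export
plot_pressure_trial <- function(series, mask = NULL, force_threshold = 35,
                                min_duration = 0.1) {
  geom <- pf_attr(series, "geometry")
  mask <- mask %||% region_mask(
    geom, center_mm = default_ulcer_xy(pf_attr(series, "dialect")),
    radius_mm = 15
  )
  curve <- apply(as.matrix(series[mask$sensors]), 1, max)
  phases <- detect_stance_phases(series, force_threshold, min_duration)
  df <- tibble(time_s = series$time_s, kpa = curve)
  shade <- tibble(xmin = series$time_s[phases$start],
                  xmax = series$time_s[pmin(phases$end, nrow(series))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$kpa)) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "orange", alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Ulcer-site pressure (kPa)",
                  title = "Regional pressure curve with detected stances")
}

#' @rdname cpts_result
#' @param object A `cpts_result` (autoplot) .
#' @method autoplot cpts_result
#' @export
autoplot.cpts_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_day,
                            dplyr::any_of(c("cpts_model1", "cpts_model2")),
                            names_to = "model", values_to = "cpts") |>
    dplyr::filter(is.finite(.data$cpts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$cpts,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "CPTS (MPa·s)",
                  title = "Daily cumulative plantar tissue stress")
}

#' @rdname run_cohort
#' @param object A `cohort_report` (autoplot).
#' @method autoplot cohort_report
#' @export
autoplot.cohort_report <- function(object, ...) {
  cmp <- object$comparison
  df <- dplyr::bind_rows(
    tibble(variable = cmp$variable, group = "healed",
           median = cmp$median_healed, p25 = cmp$p25_healed,
           p75 = cmp$p75_healed),
    tibble(variable = cmp$variable, group = "non-healed",
           median = cmp$median_non_healed, p25 = cmp$p25_non_healed,
           p75 = cmp$p75_non_healed)
  ) |> dplyr::filter(is.finite(.data$median))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median, y = .data$variable,
                                   colour = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$p25, xmax = .data$p75),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "median [IQR] (log scale)", y = NULL,
                  title = "Healed vs non-healed: CPTS and underlying factors")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
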