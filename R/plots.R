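# ggplot2 views of nights, cycles and fits

#' Plot one preprocessed night
#'
#' Shows the skin, ambient and estimated-CBT traces with each minute
#' coloured by its validity status, and shades the analysis window.
#'
#' @param data Output of [preprocess_night()].
#' @param config The [preprocess_config()] used (for the window shading).
#' @return A ggplot object.
#' @export
plot_night <- function(data, config = preprocess_config()) {
  long <- data %>%
    select("timestamp", "status",
      skin = "skin_temp_c", ambient = "ambient_temp_c",
      `estimated CBT` = "cbt_est_c"
    ) %>%
    tidyr::pivot_longer(c("skin", "ambient", "estimated CBT"),
      names_to = "channel", values_to = "temp_c"
    )
  w0 <- data$timestamp[1] + 60 * config$window_discard_min
  w1 <- w0 + 60 * config$window_length_min
  ggplot(long, aes(.data$timestamp, .data$temp_c)) +
    annotate("rect",
      xmin = w0, xmax = w1, ymin = -Inf, ymax = Inf,
      alpha = 0.08, fill = "steelblue"
    ) +
    geom_point(aes(colour = .data$status), size = 0.4) +
    facet_wrap(~channel, scales = "free_y", ncol = 1) +
    labs(
      x = NULL, y = "temperature (°C)", colour = NULL,
      title = "Night recording",
      subtitle = "shaded region: 4-hour analysis window after the first-hour discard"
    ) +
    theme_minimal()
}

#' Plot a day-level cycle with its detected shift
#'
#' Draws the daily temperatures, the coverline implied by the accepted
#' detection's reference window (its maximum plus the threshold), and marks
#' the shift onset.
#'
#' @param series Day-level tibble with `cycle_day` and a temperature column.
#' @param classification Optional one-row output of [classify_cycle()] for
#'   the same series.
#' @inheritParams detect_shifts
#' @return A ggplot object.
#' @export
plot_cycle <- function(series, classification = NULL, temp = temp_c,
                       day = cycle_day, threshold = 0.2) {
  d <- tibble(
    cycle_day = dplyr::pull(series, {{ day }}),
    temp_c = dplyr::pull(series, {{ temp }})
  )
  p <- ggplot(d, aes(.data$cycle_day, .data$temp_c)) +
    geom_line(na.rm = TRUE, colour = "grey60") +
    geom_point(na.rm = TRUE) +
    labs(
      x = "cycle day", y = "temperature (°C)",
      title = "Daily temperature series"
    ) +
    theme_minimal()
  if (!is.null(classification) && classification$status[1] == "biphasic") {
    det <- classification$detections[[1]]
    det <- det[det$onset_day == classification$onset_day[1], ][1, ]
    p <- p +
      geom_hline(
        yintercept = det$reference_max + threshold,
        linetype = "dashed", colour = "firebrick"
      ) +
      geom_vline(
        xintercept = classification$onset_day[1],
        linetype = "dotted", colour = "firebrick"
      ) +
      labs(subtitle = sprintf(
        "biphasic: onset day %d (%s); dashed line = reference max + %.1f °C",
        classification$onset_day[1], classification$rule_variant[1], threshold
      ))
  } else if (!is.null(classification)) {
    p <- p + labs(subtitle = "monophasic: no accepted shift")
  }
  p
}

#' @describeIn fit_thermal_coefficient Autoplot: calibration scatter with
#'   the fitted regression line.
#' @param object A `thermal_model`; `data` the calibration pairs it was
#'   fitted on.
#' @method autoplot thermal_model
#' @export
autoplot.thermal_model <- function(object, data, skin = skin_temp_c,
                                   ambient = ambient_temp_c, ...) {
  d <- tibble(
    skin = dplyr::pull(data, {{ skin }}),
    ambient = dplyr::pull(data, {{ ambient }})
  )
  ggplot(d, aes(.data$ambient, .data$skin)) +
    geom_point(alpha = 0.4, size = 0.6) +
    geom_abline(
      slope = object$alpha,
      intercept = mean(d$skin, na.rm = TRUE) - object$alpha * mean(d$ambient, na.rm = TRUE),
      colour = "firebrick"
    ) +
    labs(
      x = "ambient (°C)", y = "skin (°C)",
      title = sprintf("K calibration: alpha = %.3f, K = %.3f", object$alpha, object$k)
    ) +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
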