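# Heat-flux estimation of core body temperature (CBT) from paired chest
# skin and ambient temperature, plus the nightly reduction to one
# representative temperature.
#
# Physical model: conductive heat flow from the core through the body
# (conductivity lambda1) and onward through the sensor stack to the air
# (conductivity lambda2). Equating the two fluxes gives
#   CBT = Ts + K (Ts - Ta),  K = lambda2 / lambda1,
# so a single dimensionless coefficient K carries all the physics. K is
# calibrated from data: the forward model Ts = (K Ta + CBT) / (1 + K)
# is linear in Ta with slope alpha = K / (1 + K), hence K = alpha / (1 - alpha).

# plausibility bounds for raw sensor readings (degrees C)
.SKIN_RANGE <- c(15, 45)
.AMBIENT_RANGE <- c(-10, 45)

#' Estimate core body temperature from skin and ambient temperature
#'
#' Applies the heat-flux estimator `CBT = Ts + K (Ts - Ta)`: the skin
#' temperature is corrected upward by the temperature drop across the body,
#' inferred from the drop across the sensor and the conductivity ratio `K`.
#'
#' @param skin_temp Skin temperature in degrees Celsius (vectorised).
#' @param ambient_temp Ambient temperature in degrees Celsius (vectorised,
#'   recycled against `skin_temp`).
#' @param k Dimensionless thermal-conductivity ratio (sensor over body),
#'   `k >= 0`. `k = 0` returns the skin temperature unchanged.
#'
#' @return A numeric vector of estimated core body temperatures (degrees C),
#'   at full floating precision (no rounding).
#'
#' @examples
#' estimate_cbt(36.0, 24.0, k = 0.05) # 36.6
#' @export
estimate_cbt <- function(skin_temp, ambient_temp, k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k)) {
    abort("`k` must be a single finite number.", class = "ovushift_error_parameter")
  }
  if (k < 0) {
    abort("`k` must be non-negative (it is a ratio of conductivities).",
      class = "ovushift_error_parameter"
    )
  }
  if (!all(is.finite(skin_temp)) || !all(is.finite(ambient_temp))) {
    abort("`skin_temp` and `ambient_temp` must be finite.",
      class = "ovushift_error_input"
    )
  }
  skin_temp + k * (skin_temp - ambient_temp)
}

#' Calibrate the heat-flux coefficient K from paired readings
#'
#' Regresses skin temperature on ambient temperature by ordinary least
#' squares. Under the heat-flux model the slope is `alpha = K / (1 + K)`,
#' so `K = alpha / (1 - alpha)`. Calibration pairs should span a range of
#' ambient temperatures while the true core temperature is (approximately)
#' stable; pooling nights across subjects yields a general-purpose K.
#'
#' @param data A data frame of calibration pairs.
#' @param skin,ambient Columns of `data` holding skin and ambient temperature
#'   (degrees C); tidy-eval, defaults `skin_temp_c` / `ambient_temp_c`.
#'
#' @return A `thermal_model` object with elements `k`, `alpha`, `n_points`,
#'   `residual_sd` and `clamped` (TRUE when a negative fitted slope was
#'   clamped to zero). Supports [tidy()] and [glance()].
#'
#' @details A fitted `alpha < 0` (skin temperature falling as ambient rises)
#'   contradicts the model; the slope is clamped to 0 with a warning, giving
#'   `K = 0`. `alpha >= 1` would imply infinite or negative conductivity and
#'   is refused. Readings outside plausibility bounds (skin 15-45, ambient
#'   -10 to 45) are dropped from the fit with a warning.
#'
#' @examples
#' pairs <- tibble::tibble(
#'   ambient_temp_c = seq(18, 30, length.out = 50),
#'   skin_temp_c = (0.2 * ambient_temp_c + 36.8) / 1.2
#' )
#' fit_thermal_coefficient(pairs)$k # 0.2
#' @export
fit_thermal_coefficient <- function(data, skin = skin_temp_c,
                                    ambient = ambient_temp_c) {
  skin <- dplyr::pull(data, {{ skin }})
  ambient <- dplyr::pull(data, {{ ambient }})
  ok <- is.finite(skin) & is.finite(ambient) &
    skin >= .SKIN_RANGE[1] & skin <= .SKIN_RANGE[2] &
    ambient >= .AMBIENT_RANGE[1] & ambient <= .AMBIENT_RANGE[2]
  if (any(!ok)) {
    warn(sprintf("%d calibration pair(s) outside plausibility bounds dropped.", sum(!ok)))
  }
  skin <- skin[ok]
  ambient <- ambient[ok]
  if (length(skin) < 10) {
    abort("At least 10 valid calibration pairs are required.",
      class = "ovushift_error_input"
    )
  }
  if (var(ambient) == 0) {
    abort("Ambient temperature is constant: the slope is unidentifiable.",
      class = "ovushift_error_degenerate"
    )
  }
  fit <- lm(skin ~ ambient)
  alpha <- unname(coef(fit)[2])
  clamped <- FALSE
  if (alpha >= 1) {
    abort(sprintf(
      "Fitted slope alpha = %.3f >= 1: incompatible with the heat-flux model.",
      alpha
    ), class = "ovushift_error_model")
  }
  if (alpha < 0) {
    warn(sprintf(
      "Fitted slope alpha = %.3f < 0 clamped to 0 (skin temperature should not fall with rising ambient).",
      alpha
    ))
    alpha <- 0
    clamped <- TRUE
  }
  structure(
    list(
      k = alpha / (1 - alpha),
      alpha = alpha,
      n_points = length(skin),
      residual_sd = sd(stats::residuals(fit)),
      clamped = clamped
    ),
    class = "thermal_model"
  )
}

#' Construct a thermal model from a known coefficient
#'
#' Wraps a fixed `K` (for example one supplied by a device vendor) in the
#' same object [fit_thermal_coefficient()] returns, so downstream functions
#' accept either.
#'
#' @param k Non-negative thermal-conductivity ratio.
#' @return A `thermal_model` object.
#' @export
thermal_model <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k < 0) {
    abort("`k` must be a single non-negative number.", class = "ovushift_error_parameter")
  }
  structure(
    list(k = k, alpha = k / (1 + k), n_points = NA_integer_,
         residual_sd = NA_real_, clamped = FALSE),
    class = "thermal_model"
  )
}

#' @export
print.thermal_model <- function(x, ...) {
  cat("Heat-flux thermal model\n")
  cat(sprintf("  K = %.4f (alpha = %.4f)\n", x$k, x$alpha))
  if (!is.na(x$n_points)) {
    cat(sprintf("  fitted on %d pairs, residual sd %.3f degC\n",
                x$n_points, x$residual_sd))
  }
  invisible(x)
}

#' Preprocessing configuration for night recordings
#'
#' @param window_discard_min Minutes discarded at the start of each recording
#'   while the sensor's heat flux stabilises (default 60).
#' @param window_length_min Length of the analysis window that follows the
#'   discard period, in minutes (default 240).
#' @param max_step Largest physiologically plausible change in estimated CBT
#'   between consecutive valid minutes, degrees C (default 0.3); larger jumps
#'   start an artifact run.
#' @param max_ambient_step Largest plausible minute-to-minute ambient change,
#'   degrees C (default 2); larger jumps signal sensor displacement.
#' @param min_valid_fraction Minimum fraction of the analysis window that must
#'   survive exclusion for the night to yield a representative temperature
#'   (default 0.5).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(window_discard_min = 60, window_length_min = 240,
                              max_step = 0.3, max_ambient_step = 2,
                              min_valid_fraction = 0.5) {
  stopifnot(
    window_discard_min >= 0, window_length_min > 0,
    max_step > 0, max_ambient_step > 0,
    min_valid_fraction >= 0, min_valid_fraction <= 1
  )
  structure(
    list(
      window_discard_min = window_discard_min,
      window_length_min = window_length_min,
      max_step = max_step,
      max_ambient_step = max_ambient_step,
      min_valid_fraction = min_valid_fraction
    ),
    class = "preprocess_config"
  )
}

#' Flag each minute of a night recording as valid or excluded
#'
#' Implements the nightly screening protocol: the first hour after the sensor
#' is applied is discarded as unreliable, the following four hours form the
#' analysis window, minutes where ambient exceeds skin temperature are
#' excluded (external heat defeats the flux model), and abrupt jumps in the
#' estimated CBT or in ambient temperature are treated as artifact runs
#' (sensor displacement) that last until the estimate returns to within
#' `max_step` of its last pre-artifact value.
#'
#' @param data A data frame of one night's minute-level samples, in time
#'   order, with columns `timestamp`, `skin_temp_c`, `ambient_temp_c`.
#' @param model A `thermal_model` (used to estimate CBT for the artifact rule).
#' @param config A [preprocess_config()].
#'
#' @return The input tibble with columns `cbt_est_c` and `status` added;
#'   `status` is one of `out_of_window`, `valid`, `excluded_ambient`,
#'   `excluded_artifact`, `invalid_range`. An attribute `truncated` marks
#'   windows shorter than `window_length_min`.
#' @export
preprocess_night <- function(data, model, config = preprocess_config()) {
  stopifnot(inherits(model, "thermal_model"), inherits(config, "preprocess_config"))
  if (nrow(data) == 0) {
    abort("Empty night recording.", class = "ovushift_error_input")
  }
  ts <- data$timestamp
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    abort("Timestamps must be strictly increasing.", class = "ovushift_error_input")
  }
  minutes <- as.numeric(difftime(ts, ts[1], units = "mins"))
  if (max(minutes) < config$window_discard_min) {
    abort(sprintf(
      "Recording shorter than the %d-minute discard period.",
      config$window_discard_min
    ), class = "ovushift_error_too_short")
  }
  in_window <- minutes >= config$window_discard_min &
    minutes < config$window_discard_min + config$window_length_min
  truncated <- max(minutes) < config$window_discard_min + config$window_length_min - 1

  skin <- data$skin_temp_c
  amb <- data$ambient_temp_c
  cbt <- skin + model$k * (skin - amb)

  status <- rep("out_of_window", nrow(data))
  plausible <- is.finite(skin) & is.finite(amb) &
    skin >= .SKIN_RANGE[1] & skin <= .SKIN_RANGE[2] &
    amb >= .AMBIENT_RANGE[1] & amb <= .AMBIENT_RANGE[2]
  status[in_window & !plausible] <- "invalid_range"
  status[in_window & plausible & amb > skin] <- "excluded_ambient"

  # artifact scan over the remaining in-window candidates, in time order
  idx <- which(in_window & plausible & !(amb > skin))
  last_valid <- NA_real_ # estimated CBT of the last valid minute
  in_artifact <- FALSE
  prev_amb <- NA_real_ # ambient of the previous candidate minute
  for (i in idx) {
    jump <- !is.na(last_valid) && (
      abs(cbt[i] - last_valid) > config$max_step ||
        (!is.na(prev_amb) && abs(amb[i] - prev_amb) > config$max_ambient_step)
    )
    if (in_artifact) {
      # run ends when the estimate returns near the pre-artifact level
      if (abs(cbt[i] - last_valid) <= config$max_step &&
          (is.na(prev_amb) || abs(amb[i] - prev_amb) <= config$max_ambient_step)) {
        in_artifact <- FALSE
        status[i] <- "valid"
        last_valid <- cbt[i]
      } else {
        status[i] <- "excluded_artifact"
      }
    } else if (jump) {
      in_artifact <- TRUE
      status[i] <- "excluded_artifact"
    } else {
      status[i] <- "valid"
      last_valid <- cbt[i]
    }
    prev_amb <- amb[i]
  }

  out <- dplyr::mutate(as_tibble(data), cbt_est_c = cbt, status = status)
  attr(out, "truncated") <- truncated
  if (truncated) {
    warn("Recording ends before the full 4-hour analysis window; proceeding on the truncated window.")
  }
  out
}

#' Reduce one night recording to a representative temperature
#'
#' Runs [preprocess_night()] and averages the estimated CBT over the valid
#' minutes of the analysis window. Nights where fewer than
#' `min_valid_fraction` of the window minutes survive are flagged
#' `insufficient_data` and yield a missing representative temperature.
#'
#' @inheritParams preprocess_night
#' @return A one-row tibble: `representative_temp_c`, `n_valid`,
#'   `n_excluded_ambient`, `n_excluded_artifact`, `window_start`,
#'   `window_end`, `quality_flag` (`ok`, `insufficient_data` or `too_short`).
#' @export
summarize_night <- function(data, model, config = preprocess_config()) {
  flagged <- tryCatch(
    preprocess_night(data, model, config),
    ovushift_error_too_short = function(e) NULL
  )
  if (is.null(flagged)) {
    return(tibble(
      representative_temp_c = NA_real_, n_valid = 0L,
      n_excluded_ambient = 0L, n_excluded_artifact = 0L,
      window_start = data$timestamp[1], window_end = data$timestamp[1],
      quality_flag = "too_short"
    ))
  }
  in_window <- flagged$status != "out_of_window"
  n_window <- sum(in_window)
  valid <- flagged$status == "valid"
  n_valid <- sum(valid)
  rep_temp <- NA_real_
  flag <- "insufficient_data"
  # the quorum is judged against the nominal window length, so truncated
  # nights must still carry enough valid minutes
  if (n_valid >= config$min_valid_fraction * config$window_length_min &&
      n_valid > 0) {
    rep_temp <- mean(flagged$cbt_est_c[valid])
    flag <- "ok"
  }
  tibble(
    representative_temp_c = rep_temp,
    n_valid = n_valid,
    n_excluded_ambient = sum(flagged$status == "excluded_ambient"),
    n_excluded_artifact = sum(flagged$status == "excluded_artifact"),
    window_start = if (n_window) min(flagged$timestamp[in_window]) else flagged$timestamp[1],
    window_end = if (n_window) max(flagged$timestamp[in_window]) else flagged$timestamp[1],
    quality_flag = flag
  )
}

#' Summarise many nights at once
#'
#' Applies [summarize_night()] to each night of a minute-level table.
#'
#' @param data Minute-level readings for one or more nights: columns
#'   `subject_id`, `night_id`, `timestamp`, `skin_temp_c`, `ambient_temp_c`.
#' @inheritParams preprocess_night
#' @return A tibble with one row per night: identifiers, `date` (calendar
#'   date of the night's first sample), and the [summarize_night()] columns.
#' @export
summarize_nights <- function(data, model, config = preprocess_config()) {
  data %>%
    group_by(.data$subject_id, .data$night_id) %>%
    group_modify(function(d, key) {
      d <- arrange(d, .data$timestamp)
      res <- summarize_night(d, model, config)
      mutate(res, date = as.Date(d$timestamp[1]), .before = 1)
    }) %>%
    ungroup()
}
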