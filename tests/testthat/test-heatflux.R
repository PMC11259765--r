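# heat-flux estimator, K calibration, and the nightly reduction

make_night <- function(skin, ambient, n = max(length(skin), length(ambient)),
                       start = as.POSIXct("2024-01-01 23:00:00", tz = "UTC")) {
  tibble::tibble(
    timestamp = start + 60 * (seq_len(n) - 1),
    skin_temp_c = rep_len(skin, n),
    ambient_temp_c = rep_len(ambient, n)
  )
}

test_that("estimate_cbt applies the displayed equation and its edge cases", {
  expect_equal(estimate_cbt(36.0, 24.0, k = 0.05), 36.60)
  expect_equal(estimate_cbt(36.2, 36.2, k = 0.7), 36.2) # zero gradient
  expect_equal(estimate_cbt(36.0, 20.0, k = 0), 36.0) # K = 0: skin temp
  expect_error(estimate_cbt(36, 24, k = -0.1), class = "ovushift_error_parameter")
  expect_error(estimate_cbt(NaN, 24, k = 0.1), class = "ovushift_error_input")
})

test_that("estimate_cbt is increasing in skin and decreasing in ambient temperature", {
  withr::local_seed(11)
  for (i in 1:20) {
    k <- runif(1, 0, 1)
    ts <- runif(1, 34, 38)
    ta <- runif(1, 15, 30)
    d <- runif(1, 0.01, 1)
    expect_gt(estimate_cbt(ts + d, ta, k), estimate_cbt(ts, ta, k))
    if (k > 0) expect_lt(estimate_cbt(ts, ta + d, k), estimate_cbt(ts, ta, k))
  }
})

test_that("the estimator inverts the forward model to machine precision", {
  withr::local_seed(5)
  cbt <- runif(50, 36, 38)
  ta <- runif(50, 15, 30)
  k <- runif(50, 0, 2)
  ts <- (k * ta + cbt) / (1 + k)
  got <- vapply(1:50, function(i) estimate_cbt(ts[i], ta[i], k[i]), 0)
  expect_equal(got, cbt, tolerance = 1e-12)
})

test_that("K calibration recovers the generating coefficient and algebra", {
  withr::local_seed(21)
  ta <- runif(300, 18, 30)
  pairs <- tibble::tibble(
    ambient_temp_c = ta,
    skin_temp_c = (0.2 * ta + 36.8) / 1.2
  )
  fit <- fit_thermal_coefficient(pairs)
  expect_equal(fit$k, 0.2, tolerance = 1e-9)
  expect_equal(fit$alpha, fit$k / (1 + fit$k), tolerance = 1e-12)
  expect_identical(fit$n_points, 300L)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$k, fit$k)
})

test_that("K calibration refuses or clamps ill-posed fits", {
  ta <- seq(18, 30, length.out = 50)
  # constant ambient: slope unidentifiable
  expect_error(
    fit_thermal_coefficient(tibble::tibble(ambient_temp_c = rep(24, 50),
                                           skin_temp_c = rnorm(50, 36, 0.1))),
    class = "ovushift_error_degenerate"
  )
  # skin falling with ambient: clamped to alpha = 0, K = 0
  expect_warning(
    fit0 <- fit_thermal_coefficient(tibble::tibble(ambient_temp_c = ta,
                                                   skin_temp_c = 40 - 0.1 * ta)),
    "clamped"
  )
  expect_equal(fit0$k, 0)
  expect_true(fit0$clamped)
  # slope >= 1 is incompatible with the model (would need alpha < 1)
  expect_error(
    fit_thermal_coefficient(tibble::tibble(ambient_temp_c = ta,
                                           skin_temp_c = 10 + 1.1 * ta)),
    class = "ovushift_error_model"
  )
  expect_error(
    fit_thermal_coefficient(tibble::tibble(ambient_temp_c = ta[1:5],
                                           skin_temp_c = ta[1:5])),
    class = "ovushift_error_input"
  )
})

test_that("the analysis window is the 4 hours after the first-hour discard", {
  m <- thermal_model(0.05)
  night <- make_night(36.3, 25.0, 360) # 6 h from 23:00
  flagged <- preprocess_night(night, m)
  expect_identical(sum(flagged$status == "valid"), 240L)
  win <- flagged$timestamp[flagged$status != "out_of_window"]
  expect_equal(format(min(win), "%H:%M"), "00:00")
  expect_equal(format(max(win), "%H:%M"), "03:59")
  # everything before and after is out of window
  expect_true(all(flagged$status[1:60] == "out_of_window"))
  expect_true(all(flagged$status[301:360] == "out_of_window"))
})

test_that("ambient above skin temperature excludes the minute", {
  m <- thermal_model(0.05)
  night <- make_night(36.0, 25.0, 330)
  night$ambient_temp_c[100:129] <- 36.5 # 30 min of external heat
  flagged <- preprocess_night(night, m)
  expect_identical(sum(flagged$status == "excluded_ambient"), 30L)
  s <- summarize_night(night, m)
  expect_identical(s$n_excluded_ambient, 30L)
  expect_equal(s$representative_temp_c, estimate_cbt(36.0, 25.0, 0.05))
})

test_that("abrupt estimate jumps open an artifact run that ends on recovery", {
  m <- thermal_model(0.2)
  night <- make_night(36.3, 25.0, 330)
  night$skin_temp_c[150:159] <- 34.3 # 10-min displacement drop
  flagged <- preprocess_night(night, m)
  expect_identical(which(flagged$status == "excluded_artifact"), 150:159)
  s <- summarize_night(night, m)
  expect_identical(s$n_excluded_artifact, 10L)
  expect_equal(s$representative_temp_c, estimate_cbt(36.3, 25.0, 0.2))
  # an ambient jump alone also triggers the rule
  night2 <- make_night(36.3, 25.0, 330)
  night2$ambient_temp_c[200] <- 30.0
  flagged2 <- preprocess_night(night2, m)
  expect_true(flagged2$status[200] == "excluded_artifact")
})

test_that("short and truncated recordings are handled per the protocol", {
  m <- thermal_model(0.1)
  expect_error(
    preprocess_night(make_night(36.3, 25.0, 45), m),
    class = "ovushift_error_too_short"
  )
  s <- summarize_night(make_night(36.3, 25.0, 45), m)
  expect_identical(s$quality_flag, "too_short")
  expect_true(is.na(s$representative_temp_c))
  # 3 h recording: proceeds on the truncated window with a warning,
  # and 120 valid minutes of a nominal 240 meet the 0.5 quorum exactly
  expect_warning(s2 <- summarize_night(make_night(36.3, 25.0, 180), m),
                 "truncated")
  expect_identical(s2$quality_flag, "ok")
  expect_identical(s2$n_valid, 120L)
})

test_that("nights below the valid-minute quorum yield no representative temperature", {
  m <- thermal_model(0.05)
  night <- make_night(36.0, 25.0, 300)
  night$ambient_temp_c[61:200] <- 36.5 # 140 of 240 window minutes excluded
  s <- summarize_night(night, m)
  expect_identical(s$n_valid, 100L)
  expect_identical(s$quality_flag, "insufficient_data")
  expect_true(is.na(s$representative_temp_c))
})

test_that("the representative temperature is order-free and ignores trailing samples", {
  withr::local_seed(33)
  m <- thermal_model(0.1)
  night <- make_night(36.3 + runif(330, -0.02, 0.02), 25 + runif(330, -0.1, 0.1))
  base <- summarize_night(night, m)
  # permute the readings within the analysis window (timestamps fixed)
  idx <- 61:300
  perm <- sample(idx)
  night2 <- night
  night2$skin_temp_c[idx] <- night$skin_temp_c[perm]
  night2$ambient_temp_c[idx] <- night$ambient_temp_c[perm]
  expect_equal(summarize_night(night2, m)$representative_temp_c,
               base$representative_temp_c)
  # trailing out-of-window samples change nothing
  night3 <- dplyr::bind_rows(night, make_night(30, 20, 30, start = night$timestamp[330] + 60))
  expect_equal(summarize_night(night3, m)$representative_temp_c,
               base$representative_temp_c)
})

test_that("summarize_nights recovers the generating CBT from simulated nights", {
  sim <- generate_night(true_cbt = 36.9, k_true = 0.2, sensor_noise_sd = 0.05,
                        seed = 91)
  m <- thermal_model(0.2)
  s <- summarize_night(sim$minutes, m)
  expect_identical(s$quality_flag, "ok")
  expect_lt(abs(s$representative_temp_c - 36.9), 0.02)
  # grouped interface
  minutes <- dplyr::mutate(sim$minutes, subject_id = "S01", night_id = "n1")
  many <- summarize_nights(minutes, m)
  expect_identical(nrow(many), 1L)
  expect_equal(many$representative_temp_c, s$representative_temp_c)
})
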