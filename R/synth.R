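# Synthetic data generators: minute-level nights obeying the heat-flux
# forward model, and day-level menstrual cycles with a biphasic luteal rise,
# so the whole pipeline is testable without any recorded data.
#
# Day-level defaults follow the reference study conditions: follicular mean
# 36.48 degC with between-subject sd 0.22, and a between-phase rise of mean
# 0.41 / sd 0.20 degC.

#' Simulate one night of minute-level sensor data
#'
#' Forward model of the heat-flux sensor: the ambient temperature follows a
#' slow drift plus a smooth random wander, and the skin temperature obeys
#' `Ts = (K Ta + CBT) / (1 + K)` plus Gaussian sensor noise. The first
#' 45-75 minutes carry an exponentially decaying warm-up transient (the
#' sensor equilibrating after it is put on), which exercises the first-hour
#' discard; an optional displacement artifact (a 5-15 minute drop of 1-3
#' degC in skin temperature) exercises artifact rejection.
#'
#' @param true_cbt Core body temperature being simulated, degrees C.
#' @param k_true Conductivity ratio of the simulated sensor.
#' @param ambient_mean Mean ambient temperature, degrees C.
#' @param ambient_drift Linear ambient trend, degrees C per hour.
#' @param ambient_wander_sd Standard deviation of the smooth ambient wander,
#'   degrees C (0 = deterministic path).
#' @param sensor_noise_sd Per-minute Gaussian noise on the skin reading,
#'   degrees C.
#' @param artifact_prob Probability that one displacement artifact is
#'   injected inside the analysis window.
#' @param warmup_amp Amplitude of the warm-up transient on the skin reading,
#'   degrees C (negative: the sensor starts cool).
#' @param duration_min Recording length in minutes (>= 300 for a full
#'   analysis window).
#' @param start Timestamp of the first sample.
#' @param seed Optional integer seed; the generator is deterministic given
#'   the seed.
#'
#' @return A list: `minutes` (tibble `timestamp`, `skin_temp_c`,
#'   `ambient_temp_c`) and `truth` (one-row tibble with the generating
#'   parameters and any artifact window).
#' @export
generate_night <- function(true_cbt = 36.7, k_true = 0.2,
                           ambient_mean = 24, ambient_drift = -0.5,
                           ambient_wander_sd = 0.5,
                           sensor_noise_sd = 0.05, artifact_prob = 0,
                           warmup_amp = -1.5, duration_min = 420,
                           start = as.POSIXct("2024-01-01 23:00:00", tz = "UTC"),
                           seed = NULL) {
  stopifnot(duration_min >= 60, k_true >= 0, sensor_noise_sd >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  t_min <- seq_len(duration_min) - 1

  ambient <- ambient_mean + ambient_drift * t_min / 60
  if (ambient_wander_sd > 0) {
    w <- cumsum(rnorm(duration_min))
    ambient <- ambient + w / max(sd(w), .Machine$double.eps) * ambient_wander_sd
  }

  skin <- (k_true * ambient + true_cbt) / (1 + k_true) +
    rnorm(duration_min, 0, sensor_noise_sd)

  # warm-up: decays to ~0 well before the analysis window opens
  warm_dur <- runif(1, 45, 75)
  skin <- skin + warmup_amp * exp(-t_min / (warm_dur / 5))

  art_start <- NA_integer_
  art_len <- NA_integer_
  if (artifact_prob > 0 && runif(1) < artifact_prob) {
    art_len <- sample(5:15, 1)
    art_start <- sample(61:(duration_min - art_len), 1)
    drop <- runif(1, 1, 3)
    skin[art_start:(art_start + art_len - 1)] <-
      skin[art_start:(art_start + art_len - 1)] - drop
  }

  list(
    minutes = tibble(
      timestamp = start + 60 * t_min,
      skin_temp_c = skin,
      ambient_temp_c = ambient
    ),
    truth = tibble(
      true_cbt = true_cbt, k_true = k_true,
      warmup_min = warm_dur,
      artifact_start_min = art_start, artifact_len_min = art_len
    )
  )
}

#' Simulate one day-level menstrual cycle
#'
#' Generates a daily temperature series: a flat follicular baseline and, for
#' ovulatory cycles, a luteal rise that ramps in over `shift_ramp_days`
#' starting at ovulation, plus i.i.d. Gaussian day-to-day noise and random
#' missing days. A positive LH test is placed one day before ovulation (the
#' urinary surge typically precedes ovulation by a day); earlier test days
#' are negative, and anovulatory cycles test negative throughout the same
#' window.
#'
#' @param length_days Cycle length (default 28).
#' @param ovulatory Does the cycle ovulate?
#' @param follicular_mean Baseline temperature, degrees C (default 36.48).
#' @param luteal_shift Size of the luteal rise, degrees C; `NULL` (default)
#'   draws from Normal(0.41, 0.20) truncated at 0.05.
#' @param shift_ramp_days Days over which the rise completes (default 2).
#' @param ovulation_day Day of ovulation; `NULL` draws
#'   `length_days - 14` plus integer jitter on -2..2. Must lie in
#'   `[10, length_days - 10]`.
#' @param ramp_shape `"logistic"` (default, smooth) or `"linear"`.
#' @param daily_noise_sd Day-to-day noise sd, degrees C (default 0.10).
#' @param missing_prob Probability each day's temperature is missing
#'   (default 0.10).
#' @param lh_start_day First day of LH testing (default 8, after menses).
#' @param seed Optional integer seed.
#'
#' @return A list: `days` (tibble `cycle_day`, `temp_c`, `lh_result`) and
#'   `truth` (one-row tibble `ovulatory`, `ovulation_day`, `luteal_shift`).
#' @export
generate_cycle <- function(length_days = 28, ovulatory = TRUE,
                           follicular_mean = 36.48, luteal_shift = NULL,
                           shift_ramp_days = 2, ovulation_day = NULL,
                           ramp_shape = c("logistic", "linear"),
                           daily_noise_sd = 0.10, missing_prob = 0.10,
                           lh_start_day = 8, seed = NULL) {
  ramp_shape <- match.arg(ramp_shape)
  stopifnot(length_days >= 15, daily_noise_sd >= 0,
            missing_prob >= 0, missing_prob <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(luteal_shift)) {
    luteal_shift <- max(0.05, rnorm(1, 0.41, 0.20))
  }
  if (is.null(ovulation_day)) {
    ovulation_day <- length_days - 14 + sample(-2:2, 1)
  }
  if (ovulation_day < 10 || ovulation_day > length_days - 10) {
    abort("`ovulation_day` must lie in [10, length_days - 10].",
      class = "ovushift_error_parameter"
    )
  }

  day <- seq_len(length_days)
  ramp <- if (!ovulatory) {
    rep(0, length_days)
  } else if (ramp_shape == "linear") {
    pmin(pmax((day - ovulation_day) / shift_ramp_days, 0), 1)
  } else {
    # centred half a day after ovulation: the rise is mostly complete on
    # day ov+1, mirroring the rapid post-ovulatory progesterone effect
    plogis(8 * (day - ovulation_day - 0.5) / shift_ramp_days)
  }
  temp <- follicular_mean + ramp * luteal_shift +
    rnorm(length_days, 0, daily_noise_sd)
  temp[runif(length_days) < missing_prob] <- NA_real_

  lh <- rep(NA_character_, length_days)
  if (ovulatory) {
    surge <- ovulation_day - 1
    test_days <- lh_start_day:surge
    lh[test_days] <- "negative"
    lh[surge] <- "positive"
  } else {
    lh[lh_start_day:length_days] <- "negative"
  }

  list(
    days = tibble(cycle_day = day, temp_c = temp, lh_result = lh),
    truth = tibble(
      ovulatory = ovulatory,
      ovulation_day = if (ovulatory) ovulation_day else NA_integer_,
      luteal_shift = if (ovulatory) luteal_shift else 0
    )
  )
}

#' Simulate a study-shaped cohort
#'
#' Generates a day-level table covering `n_cycles` menstrual cycles spread
#' as evenly as possible over `n_subjects` subjects, with per-subject
#' baselines drawn Normal(`follicular_mean`, `between_subject_sd`). Each
#' cycle yields two daily temperature series sharing the same ovulation day
#' and luteal shift: an estimated-CBT series (`cbt_est_c`) and an oral-BBT
#' series (`oral_bbt_c`) with attenuated shift and larger noise, reflecting
#' the lower signal-to-noise of a single waking oral measurement.
#'
#' @param n_subjects Number of subjects (default 26).
#' @param n_cycles Total cycles (default 74).
#' @param ovulatory_fraction Fraction of cycles that ovulate (default
#'   60/74); the ovulatory count is `round(ovulatory_fraction * n_cycles)`
#'   exactly.
#' @param cycle_length_days Length of every cycle (default 28).
#' @param follicular_mean,between_subject_sd Baseline distribution, degrees
#'   C (defaults 36.48, 0.22).
#' @param luteal_shift_mean,luteal_shift_sd Luteal-rise distribution,
#'   degrees C (defaults 0.41, 0.20, truncated at 0.05); pass
#'   `luteal_shift_sd = 0` to fix the shift at `luteal_shift_mean`.
#' @param cbt_noise_sd,bbt_noise_sd Day-to-day noise sd per source
#'   (defaults 0.10, 0.15).
#' @param bbt_shift_factor Attenuation of the luteal shift in the oral-BBT
#'   series (default 0.8).
#' @param missing_prob Per-day missingness per source (default 0.10).
#' @param start_date Calendar date of the first menses onset.
#' @param seed Optional integer seed; fixed seed gives identical output.
#'
#' @return A list: `daily` (tibble `subject_id`, `date`, `cbt_est_c`,
#'   `oral_bbt_c`, `lh_result`, `menses_onset`, ready for
#'   [assemble_cycles()]) and `truth` (one row per cycle: `cycle_id`,
#'   `subject_id`, `ovulatory`, `ovulation_day`, `luteal_shift`).
#' @export
generate_cohort <- function(n_subjects = 26, n_cycles = 74,
                            ovulatory_fraction = 60 / 74,
                            cycle_length_days = 28,
                            follicular_mean = 36.48, between_subject_sd = 0.22,
                            luteal_shift_mean = 0.41, luteal_shift_sd = 0.20,
                            cbt_noise_sd = 0.10, bbt_noise_sd = 0.15,
                            bbt_shift_factor = 0.8, missing_prob = 0.10,
                            start_date = as.Date("2024-01-01"), seed = NULL) {
  stopifnot(n_subjects >= 1, n_cycles >= n_subjects,
            ovulatory_fraction >= 0, ovulatory_fraction <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  start_date <- as.Date(start_date)

  # spread cycles over subjects as evenly as possible
  per_subject <- rep(n_cycles %/% n_subjects, n_subjects)
  extra <- n_cycles %% n_subjects
  if (extra > 0) per_subject[seq_len(extra)] <- per_subject[seq_len(extra)] + 1

  n_ov <- round(ovulatory_fraction * n_cycles)
  ovulatory <- sample(rep(c(TRUE, FALSE), c(n_ov, n_cycles - n_ov)))

  baselines <- rnorm(n_subjects, follicular_mean, between_subject_sd)
  subj_ids <- sprintf("S%02d", seq_len(n_subjects))

  daily <- vector("list", n_subjects)
  truth <- vector("list", n_cycles)
  cyc <- 0L
  for (s in seq_len(n_subjects)) {
    rows <- vector("list", per_subject[s] + 1)
    date0 <- start_date
    for (j in seq_len(per_subject[s])) {
      cyc <- cyc + 1L
      shift <- if (luteal_shift_sd > 0) {
        max(0.05, rnorm(1, luteal_shift_mean, luteal_shift_sd))
      } else {
        luteal_shift_mean
      }
      ov_day <- cycle_length_days - 14 + sample(-2:2, 1)
      base <- generate_cycle(
        length_days = cycle_length_days, ovulatory = ovulatory[cyc],
        follicular_mean = baselines[s], luteal_shift = shift,
        ovulation_day = ov_day,
        daily_noise_sd = cbt_noise_sd, missing_prob = missing_prob
      )
      # oral-BBT series: same latent cycle, attenuated shift, noisier reading
      bbt <- generate_cycle(
        length_days = cycle_length_days, ovulatory = ovulatory[cyc],
        follicular_mean = baselines[s],
        luteal_shift = shift * bbt_shift_factor,
        ovulation_day = ov_day,
        daily_noise_sd = bbt_noise_sd, missing_prob = missing_prob
      )
      cycle_id <- sprintf("%s_c%02d", subj_ids[s], j)
      truth[[cyc]] <- mutate(base$truth,
        cycle_id = cycle_id, subject_id = subj_ids[s], .before = 1
      )
      rows[[j]] <- tibble(
        subject_id = subj_ids[s],
        date = date0 + base$days$cycle_day - 1,
        cbt_est_c = base$days$temp_c,
        oral_bbt_c = bbt$days$temp_c,
        lh_result = base$days$lh_result,
        menses_onset = as.integer(base$days$cycle_day == 1)
      )
      date0 <- date0 + cycle_length_days
    }
    # terminal onset closes the subject's last cycle
    rows[[per_subject[s] + 1]] <- tibble(
      subject_id = subj_ids[s], date = date0,
      cbt_est_c = NA_real_, oral_bbt_c = NA_real_,
      lh_result = NA_character_, menses_onset = 1L
    )
    daily[[s]] <- bind_rows(rows)
  }

  list(daily = bind_rows(daily), truth = bind_rows(truth))
}
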