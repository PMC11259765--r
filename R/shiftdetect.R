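# Biphasic temperature-shift detection: the "three-over-six" rule with its
# two classical exceptions, a missing-data provision for the reference
# window, and the last-14-days validity rule for accepting a shift.
#
# Rule, in words: a shift begins on the first of 3 consecutive daily
# temperatures that are each at least `threshold` (default 0.2 degC) above
# the highest of the previous 6 days. The reference window may be judged on
# as few as 4 of those 6 days when data are missing. Exceptions (mutually
# exclusive, first match wins):
#   * fourth-measurement: the third rising value clears the reference
#     maximum but by less than the threshold; the next recorded measurement
#     must then clear the reference maximum (by any margin) to confirm.
#   * disregard: exactly one of the three rising values drops to or below
#     the *average* of the reference window; it is disregarded and replaced
#     by the next recorded measurement, and the replacement-completed third
#     rising value must clear that average by the threshold.

# comparisons are made on temperatures rounded to 0.01 degC, with a small
# guard so "at least 0.2 degC higher" tolerates float representation
.EPS <- 1e-9
.round2 <- function(x) round(x, 2)

#' Detect biphasic temperature shifts with the three-over-six rule
#'
#' Scans a day-level temperature series for shift onsets: days on which a
#' sustained rise of at least `threshold` degrees above the previous six
#' days begins. Returns every confirmed detection; use [classify_cycle()] to
#' apply the last-14-days validity rule and call the cycle biphasic or
#' monophasic.
#'
#' @param series A data frame with one row per cycle day.
#' @param temp Column of `series` holding the daily temperature (degrees C;
#'   `NA` = missing day); tidy-eval, default `temp_c`.
#' @param day Column holding the cycle day (integer, day 1 = menses onset);
#'   default `cycle_day`. Days absent from the table count as missing.
#' @param threshold Minimum rise over the reference maximum, degrees C
#'   (default 0.2).
#' @param exclude_days Optional integer vector of cycle days to treat as
#'   missing (for externally annotated disturbances such as illness or
#'   alcohol; fever days would otherwise mimic a shift).
#'
#' @return A tibble of detections in onset order: `onset_day`,
#'   `rule_variant` (`base`, `exception_fourth`, `exception_disregard`),
#'   `reference_max`, `reference_mean`, `n_reference`, `rising_days`
#'   (list-column of the days whose values form the rising sequence).
#'   Attribute `evaluable` is `FALSE` (with an empty result) for series
#'   shorter than 10 days.
#'
#' @details A missing day breaks a run of "consecutive" measurements, so the
#'   first three rising values must sit on three consecutive recorded days;
#'   the reference window, by contrast, is evaluable with only 4 of its 6
#'   days recorded. The fourth/replacement measurement used by the
#'   exceptions is the next *recorded* measurement after the third day.
#'   Temperatures are rounded to 0.01 degC before rule evaluation.
#'
#' @examples
#' s <- tibble::tibble(cycle_day = 1:12,
#'                     temp_c = c(rep(36.2, 6), rep(36.5, 6)))
#' detect_shifts(s)
#' @export
detect_shifts <- function(series, temp = temp_c, day = cycle_day,
                          threshold = 0.2, exclude_days = integer()) {
  vals_in <- dplyr::pull(series, {{ temp }})
  days_in <- dplyr::pull(series, {{ day }})
  empty <- tibble(
    onset_day = integer(), rule_variant = character(),
    reference_max = double(), reference_mean = double(),
    n_reference = integer(), rising_days = list()
  )
  n_days <- if (length(days_in)) max(days_in) else 0L
  # dense day -> temperature vector; unobserved days are missing
  x <- rep(NA_real_, n_days)
  x[days_in] <- .round2(vals_in)
  x[intersect(exclude_days, seq_len(n_days))] <- NA_real_

  if (n_days < 10) {
    attr(empty, "evaluable") <- FALSE
    return(empty)
  }

  out <- vector("list", 0)
  for (d in 7:n_days) {
    det <- .evaluate_candidate(x, d, threshold)
    if (!is.null(det)) out[[length(out) + 1]] <- det
  }
  res <- if (length(out)) bind_rows(out) else empty
  attr(res, "evaluable") <- TRUE
  res
}

# Evaluate one candidate onset day against the rule; NULL when no shift is
# confirmed at this onset.
.evaluate_candidate <- function(x, d, threshold) {
  n_days <- length(x)
  ref <- x[(d - 6):(d - 1)]
  ref <- ref[!is.na(ref)]
  if (length(ref) < 4) return(NULL) # reference window not evaluable
  ref_max <- max(ref)
  ref_mean <- mean(ref)

  # three consecutive recorded days form the candidate rising sequence
  if (d + 2 > n_days) return(NULL)
  rise_days <- d:(d + 2)
  v <- x[rise_days]
  if (anyNA(v)) return(NULL) # a missing day breaks the run

  ge <- function(a, b) a >= b - .EPS # "at least" with float guard
  gt <- function(a, b) a > b + .EPS # strict "exceeds"
  clears <- ge(v, ref_max + threshold)

  detection <- function(variant, days) {
    tibble(
      onset_day = d, rule_variant = variant,
      reference_max = ref_max, reference_mean = ref_mean,
      n_reference = length(ref), rising_days = list(days)
    )
  }
  next_recorded <- function(after) {
    cand <- which(!is.na(x) & seq_along(x) > after)
    if (length(cand)) cand[1] else NA_integer_
  }

  if (all(clears)) {
    return(detection("base", rise_days))
  }

  # fourth-measurement exception: first two clear, the third exceeds the
  # reference maximum but falls short of the full threshold
  if (clears[1] && clears[2] && gt(v[3], ref_max) && !clears[3]) {
    d4 <- next_recorded(d + 2)
    if (!is.na(d4) && gt(x[d4], ref_max)) {
      return(detection("exception_fourth", c(rise_days, d4)))
    }
    return(NULL) # exceptions are mutually exclusive: stop here
  }

  # disregard exception: exactly one of the three drops to or below the
  # reference mean; replace it with the next recorded measurement
  low <- v <= ref_mean + .EPS
  if (sum(low) == 1) {
    kept <- rise_days[!low]
    d_rep <- next_recorded(d + 2)
    if (is.na(d_rep)) return(NULL)
    # retained original values must still clear the base criterion; the
    # replacement-completed third value is judged against the mean
    if (all(clears[!low]) && ge(x[d_rep], ref_mean + threshold)) {
      return(detection("exception_disregard", c(kept, d_rep)))
    }
  }
  NULL
}

#' Classify a cycle as biphasic or monophasic
#'
#' Applies the validity rule for shift detections: only a shift whose onset
#' falls in the final 14 days of the cycle counts (earlier rises are
#' attributed to disturbances rather than ovulation). A cycle with no
#' accepted shift is monophasic.
#'
#' @inheritParams detect_shifts
#' @param length_days Cycle length in days (menses onset to the day before
#'   the next onset). Defaults to the largest cycle day in `series`.
#' @param accept Which accepted detection to report when several fall in the
#'   window: `"earliest"` (default; the earliest plausible post-ovulatory
#'   rise) or `"latest"`.
#'
#' @return A one-row tibble: `status` (`biphasic`/`monophasic`),
#'   `onset_day`, `rule_variant` (NA when monophasic), `n_detections`, and a
#'   list-column `detections` with the full [detect_shifts()] output.
#' @export
classify_cycle <- function(series, temp = temp_c, day = cycle_day,
                           length_days = NULL, threshold = 0.2,
                           exclude_days = integer(),
                           accept = c("earliest", "latest")) {
  accept <- match.arg(accept)
  if (is.null(length_days)) {
    length_days <- max(dplyr::pull(series, {{ day }}))
  }
  dets <- detect_shifts(series, {{ temp }}, {{ day }},
    threshold = threshold, exclude_days = exclude_days
  )
  window_lo <- length_days - 13
  in_window <- dets$onset_day >= window_lo & dets$onset_day <= length_days
  hit <- dets[in_window, ]
  if (nrow(hit)) {
    pick <- if (accept == "earliest") which.min(hit$onset_day) else which.max(hit$onset_day)
    tibble(
      status = "biphasic",
      onset_day = hit$onset_day[pick],
      rule_variant = hit$rule_variant[pick],
      n_detections = nrow(dets),
      detections = list(dets)
    )
  } else {
    tibble(
      status = "monophasic",
      onset_day = NA_integer_,
      rule_variant = NA_character_,
      n_detections = nrow(dets),
      detections = list(dets)
    )
  }
}

#' Classify every cycle of an assembled cycle table
#'
#' Maps [classify_cycle()] over the output of [assemble_cycles()] for one
#' temperature source.
#'
#' @param cycles A cycle table from [assemble_cycles()] (needs the `days`
#'   list-column and `length_days`).
#' @param source Name of the temperature column inside each cycle's `days`
#'   table (e.g. `"cbt_est_c"` or `"oral_bbt_c"`).
#' @inheritParams classify_cycle
#' @return `cycles` with columns `source`, `status`, `onset_day`,
#'   `rule_variant` added (the `days` and `detections` detail columns are
#'   kept as list-columns).
#' @export
classify_cycles <- function(cycles, source, threshold = 0.2,
                            accept = c("earliest", "latest")) {
  accept <- match.arg(accept)
  stopifnot(is.character(source), length(source) == 1)
  res <- purrr::map2(cycles$days, cycles$length_days, function(d, len) {
    classify_cycle(d,
      temp = !!rlang::sym(source), day = cycle_day,
      length_days = len, threshold = threshold, accept = accept
    )
  })
  bind_cols(cycles, mutate(bind_rows(res), source = source, .before = 1))
}
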