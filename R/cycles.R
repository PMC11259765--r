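# Assembly of day-level menstrual-cycle records: split a per-subject daily
# table at menstruation onsets, attach LH test results, label ovulatory
# status, and apply the study-style inclusion filters.

#' Label a cycle's ovulatory status from its LH test results
#'
#' A urinary LH surge (any positive test) marks the cycle ovulatory; a cycle
#' with at least one recorded test and only negatives is anovulatory; a
#' cycle with no recorded test at all cannot be labelled.
#'
#' @param lh A character vector of per-day LH results: `"positive"`,
#'   `"negative"` (abbreviations `"pos"`/`"neg"` accepted), `NA` = not
#'   tested.
#' @return `"ovulatory"`, `"anovulatory"` or `"unlabelled"`.
#' @examples
#' label_ovulatory(c("neg", "neg", "pos", "neg")) # ovulatory
#' label_ovulatory(character()) # unlabelled
#' @export
label_ovulatory <- function(lh) {
  lh <- lh[!is.na(lh)]
  lh <- tolower(as.character(lh))
  bad <- !lh %in% c("positive", "negative", "pos", "neg")
  if (any(bad)) {
    abort(sprintf("Unrecognised LH result(s): %s", paste(unique(lh[bad]), collapse = ", ")),
      class = "ovushift_error_input"
    )
  }
  if (any(lh %in% c("positive", "pos"))) return("ovulatory")
  if (length(lh)) return("anovulatory")
  "unlabelled"
}

#' Assemble cycle records from a day-level table
#'
#' Splits each subject's daily observations into menstrual cycles at the
#' recorded menstruation onsets (a cycle runs from one onset to the day
#' before the next; the span after the last onset is dropped as incomplete),
#' assigns each calendar day its cycle day (onset = day 1), and labels
#' ovulatory status from the LH column via [label_ovulatory()].
#'
#' @param daily A data frame with columns `subject_id`, `date`, `menses_onset`
#'   (0/1 flag), `lh_result` (optional; `"positive"`/`"negative"`/`NA`), and
#'   one or more temperature columns named in `sources`.
#' @param sources Character vector of temperature column names to carry into
#'   each cycle's day table (default: whichever of `cbt_est_c`, `oral_bbt_c`
#'   are present). A nightly representative temperature for the night
#'   starting on date d is assigned to the cycle day containing d; an oral
#'   BBT taken on waking on day d belongs to day d.
#' @param min_length_days Cycles shorter than this are flagged `too_short`
#'   and excluded (default 15: shorter cycles cannot host a 6-day reference,
#'   a 3-day rise and a 14-day tail).
#'
#' @return A tibble with one row per cycle: `cycle_id`, `subject_id`,
#'   `start_date`, `length_days`, `label`, `n_lh_tests`, `too_short`, and a
#'   list-column `days` (tibbles with `cycle_day`, `date`, the `sources`
#'   columns, `lh_result`). Run [apply_inclusion_filters()] next.
#' @export
assemble_cycles <- function(daily, sources = NULL, min_length_days = 15) {
  if (is.null(sources)) {
    sources <- intersect(c("cbt_est_c", "oral_bbt_c"), names(daily))
  }
  missing_cols <- setdiff(c("subject_id", "date", "menses_onset", sources), names(daily))
  if (length(missing_cols)) {
    abort(paste("Missing column(s):", paste(missing_cols, collapse = ", ")),
      class = "ovushift_error_input"
    )
  }
  if (!"lh_result" %in% names(daily)) daily$lh_result <- NA_character_
  daily <- daily %>%
    mutate(date = as.Date(.data$date)) %>%
    arrange(.data$subject_id, .data$date)
  if (anyDuplicated(daily[c("subject_id", "date")])) {
    abort("Duplicate subject/date rows.", class = "ovushift_error_input")
  }

  one_subject <- function(d, key) {
    onsets <- d$date[d$menses_onset %in% 1]
    if (length(onsets) < 2) return(tibble())
    purrr::map_dfr(seq_len(length(onsets) - 1), function(i) {
      start <- onsets[i]
      len <- as.integer(onsets[i + 1] - start)
      days <- tibble(
        cycle_day = seq_len(len),
        date = start + seq_len(len) - 1
      ) %>%
        left_join(
          select(d, "date", dplyr::all_of(sources), "lh_result"),
          by = "date"
        )
      tibble(
        cycle_id = sprintf("%s_c%02d", key$subject_id, i),
        start_date = start,
        length_days = len,
        label = label_ovulatory(days$lh_result),
        n_lh_tests = sum(!is.na(days$lh_result)),
        too_short = len < min_length_days,
        days = list(days)
      )
    })
  }

  out <- daily %>%
    group_by(.data$subject_id) %>%
    group_modify(one_subject) %>%
    ungroup()
  if (nrow(out) == 0) {
    return(tibble(
      cycle_id = character(), subject_id = character(),
      start_date = as.Date(character()), length_days = integer(),
      label = character(), n_lh_tests = integer(), too_short = logical(),
      days = list()
    ))
  }
  relocate(out, "cycle_id")
}

#' Apply the study-style cycle inclusion filters
#'
#' Excludes cycles that cannot be scored against the LH reference: cycles
#' with no LH result at all (`missing_lh`), and cycles where any temperature
#' source is missing on more than `max_missing` of the cycle's days
#' (`missing_temps`; the whole cycle is dropped for all sources, keeping the
#' paired method comparison on a common cycle set). Cycles flagged
#' `too_short` by [assemble_cycles()] are excluded as well.
#'
#' @param cycles Output of [assemble_cycles()].
#' @param sources Temperature columns to check (default: those present in
#'   the `days` tables among `cbt_est_c`, `oral_bbt_c`).
#' @param max_missing Maximum tolerated missing-day fraction per source
#'   (default 0.30).
#' @return `cycles` with logical `included` and character `exclusion_reason`
#'   columns added (reason `NA` when included). Idempotent.
#' @export
apply_inclusion_filters <- function(cycles, sources = NULL, max_missing = 0.30) {
  if (is.null(sources)) {
    sources <- intersect(c("cbt_est_c", "oral_bbt_c"), names(cycles$days[[1]]))
  }
  frac_missing <- purrr::map_dbl(cycles$days, function(d) {
    max(purrr::map_dbl(sources, ~ mean(is.na(d[[.x]]))))
  })
  cycles %>%
    select(-dplyr::any_of(c("included", "exclusion_reason"))) %>%
    mutate(
      exclusion_reason = dplyr::case_when(
        .data$too_short ~ "too_short",
        .data$label == "unlabelled" ~ "missing_lh",
        frac_missing > max_missing ~ "missing_temps",
        TRUE ~ NA_character_
      ),
      included = is.na(.data$exclusion_reason)
    )
}
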