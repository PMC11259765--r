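# CSV readers/writers for the two table dialects the tool exchanges

#' Read minute-level sensor recordings
#'
#' Columns: `subject_id`, `night_id`, `timestamp` (ISO-8601),
#' `skin_temp_c`, `ambient_temp_c`; one row per minute.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_minute_csv <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      night_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      skin_temp_c = readr::col_double(),
      ambient_temp_c = readr::col_double()
    )
  )
}

#' Read a day-level table
#'
#' Columns: `subject_id`, `date`, optional `cbt_est_c` and/or `oral_bbt_c`,
#' optional `lh_result` (`positive`/`negative`, empty = not tested),
#' `menses_onset` (0/1).
#'
#' @param path CSV file path.
#' @return A tibble ready for [assemble_cycles()].
#' @export
read_daily_csv <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      date = readr::col_date(),
      lh_result = readr::col_character(),
      menses_onset = readr::col_integer(),
      .default = readr::col_double()
    )
  )
}

#' Write a tibble as CSV (thin readr wrapper, reported temps to 0.01 degC)
#'
#' @param x Tibble to write; numeric columns ending in `_c` are rounded to
#'   2 decimals for reporting.
#' @param path Destination.
#' @return `x`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  x <- mutate(x, across(dplyr::ends_with("_c") & dplyr::where(is.numeric),
    ~ round(.x, 2)))
  readr::write_csv(x, path)
  invisible(x)
}
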