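# Independent brute-force reference implementation of the three-over-six
# rule, written as a literal transcription of the rule text with plain
# loops and if-chains. Deliberately shares no code with detect_shifts().
#
# x: dense vector of daily temperatures (NA = missing), already on the
# 0.01 degC reporting grid. Returns a data.frame of onset_day/rule_variant.
oracle_three_over_six <- function(x, threshold = 0.2) {
  eps <- 1e-9
  onsets <- integer(0)
  variants <- character(0)
  n <- length(x)
  d <- 7
  while (d <= n) {
    ref <- c()
    for (j in (d - 6):(d - 1)) if (!is.na(x[j])) ref <- c(ref, x[j])
    if (length(ref) >= 4 && d + 2 <= n &&
        !is.na(x[d]) && !is.na(x[d + 1]) && !is.na(x[d + 2])) {
      M <- max(ref)
      A <- mean(ref)
      v1 <- x[d]; v2 <- x[d + 1]; v3 <- x[d + 2]
      # next recorded measurement after day d+2, if any
      v4 <- NA; j <- d + 3
      while (j <= n) {
        if (!is.na(x[j])) { v4 <- x[j]; break }
        j <- j + 1
      }
      hit <- NULL
      if (v1 >= M + threshold - eps &&
          v2 >= M + threshold - eps &&
          v3 >= M + threshold - eps) {
        hit <- "base"
      } else if (v1 >= M + threshold - eps &&
                 v2 >= M + threshold - eps &&
                 v3 > M + eps && v3 < M + threshold - eps) {
        # fourth-measurement exception; mutually exclusive with disregard
        if (!is.na(v4) && v4 > M + eps) hit <- "exception_fourth"
      } else {
        low1 <- v1 <= A + eps
        low2 <- v2 <= A + eps
        low3 <- v3 <= A + eps
        if (low1 + low2 + low3 == 1 && !is.na(v4)) {
          kept <- c(v1, v2, v3)[!c(low1, low2, low3)]
          if (all(kept >= M + threshold - eps) && v4 >= A + threshold - eps) {
            hit <- "exception_disregard"
          }
        }
      }
      if (!is.null(hit)) {
        onsets <- c(onsets, d)
        variants <- c(variants, hit)
      }
    }
    d <- d + 1
  }
  data.frame(onset_day = onsets, rule_variant = variants,
             stringsAsFactors = FALSE)
}

# random length-12 series on a small temperature grid with at most one
# missing day, for oracle-equivalence sweeps
random_grid_series <- function(grid = c(36.2, 36.3, 36.5), len = 12) {
  x <- sample(grid, len, replace = TRUE)
  if (runif(1) < 0.5) x[sample.int(len, 1)] <- NA_real_
  x
}

# dense vector -> tibble in the shape detect_shifts() consumes
as_series <- function(x) {
  tibble::tibble(cycle_day = seq_along(x), temp_c = x)
}
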