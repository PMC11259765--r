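# Diagnostic-accuracy statistics against the LH reference: 2x2 contingency
# metrics, a paired McNemar comparison of two temperature methods, a
# two-proportion chi-square test, and the repeated-measures correlation.

#' Cross-tabulate biphasic calls against LH-based ovulation labels
#'
#' Builds the 2x2 contingency table with a biphasic temperature shift as the
#' positive call and LH-confirmed ovulation as the positive reference state.
#'
#' @param calls A data frame with columns `cycle_id` and `status`
#'   (`"biphasic"`/`"monophasic"`), e.g. from [classify_cycles()].
#' @param labels A data frame with columns `cycle_id` and `label`
#'   (`"ovulatory"`/`"anovulatory"`), e.g. from [assemble_cycles()] after
#'   filtering to included cycles.
#' @return An `ovu_contingency` object: counts `tp`, `fp`, `tn`, `fn`.
#' @export
build_contingency <- function(calls, labels) {
  merged <- inner_join(
    select(calls, "cycle_id", "status"),
    select(labels, "cycle_id", "label"),
    by = "cycle_id"
  )
  if (nrow(merged) == 0) {
    abort("No cycles in common between calls and labels.",
      class = "ovushift_error_input"
    )
  }
  if (nrow(merged) != nrow(calls) || nrow(merged) != nrow(labels)) {
    abort("`calls` and `labels` must cover the same cycle set.",
      class = "ovushift_error_input"
    )
  }
  if (!all(merged$label %in% c("ovulatory", "anovulatory"))) {
    abort("Labels must be 'ovulatory' or 'anovulatory' (drop unlabelled cycles first).",
      class = "ovushift_error_input"
    )
  }
  pos <- merged$status == "biphasic"
  ref <- merged$label == "ovulatory"
  contingency_table(
    tp = sum(pos & ref), fp = sum(pos & !ref),
    tn = sum(!pos & !ref), fn = sum(!pos & ref)
  )
}

#' Construct a 2x2 contingency table from counts
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts (positive call =
#'   biphasic shift; positive reference = ovulatory by LH).
#' @return An `ovu_contingency` object.
#' @export
contingency_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Cell counts must be non-negative integers.", class = "ovushift_error_input")
  }
  if (sum(counts) == 0) {
    abort("Empty contingency table.", class = "ovushift_error_input")
  }
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
    class = "ovu_contingency"
  )
}

#' @export
print.ovu_contingency <- function(x, ...) {
  cat("2x2 contingency (call = biphasic shift, reference = LH ovulatory)\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
    dimnames = list(c("biphasic", "monophasic"), c("ovulatory", "anovulatory")))
  print(m)
  invisible(x)
}

#' Diagnostic-accuracy metrics from a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive value (as
#' percentages) and the F1 score (fraction). A metric whose denominator is
#' zero is reported `NA` ("undefined") without affecting the others.
#'
#' @param ct An `ovu_contingency` from [build_contingency()] or
#'   [contingency_table()].
#' @return A `diagnostic_report` object; supports [tidy()] and [glance()].
#'   Percentages carry full precision; the print method rounds to 2
#'   decimals.
#' @examples
#' compute_metrics(contingency_table(tp = 51, fp = 1, tn = 13, fn = 9))
#' @export
compute_metrics <- function(ct) {
  stopifnot(inherits(ct, "ovu_contingency"))
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  f1_den <- 2 * ct$tp + ct$fp + ct$fn
  structure(
    list(
      tp = ct$tp, fp = ct$fp, tn = ct$tn, fn = ct$fn,
      sensitivity = pct(ct$tp, ct$tp + ct$fn),
      specificity = pct(ct$tn, ct$tn + ct$fp),
      ppv = pct(ct$tp, ct$tp + ct$fp),
      npv = pct(ct$tn, ct$tn + ct$fn),
      f1 = if (f1_den > 0) 2 * ct$tp / f1_den else NA_real_
    ),
    class = "diagnostic_report"
  )
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Diagnostic accuracy (biphasic shift vs LH reference)\n")
  cat(sprintf("  n = %d (tp %d, fp %d, tn %d, fn %d)\n",
              x$tp + x$fp + x$tn + x$fn, x$tp, x$fp, x$tn, x$fn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", v)
  cat(sprintf("  sensitivity %s%%  specificity %s%%\n",
              fmt(x$sensitivity), fmt(x$specificity)))
  cat(sprintf("  PPV %s%%  NPV %s%%  F1 %s\n",
              fmt(x$ppv), fmt(x$npv), fmt(x$f1)))
  invisible(x)
}

#' Paired McNemar comparison of two classification methods
#'
#' Compares the per-cycle correctness of two methods evaluated on the same
#' cycles. With fewer than `exact_limit` discordant cycles the exact
#' two-sided binomial test on the discordant split is used; otherwise the
#' continuity-corrected chi-square statistic `(|b - c| - 1)^2 / (b + c)`.
#'
#' @param correct_a,correct_b Logical vectors: was each cycle classified
#'   correctly by method A / method B? Same length, same cycle order.
#' @param exact_limit Discordant-count threshold below which the exact test
#'   is used (default 25).
#' @return A one-row tibble: `b` (A correct, B wrong), `c` (B correct, A
#'   wrong), `statistic` (`NA` for the exact test), `p_value`, `method`.
#' @examples
#' mcnemar_counts(b = 10, c = 0) # exact p = 2 * 0.5^10
#' @export
mcnemar_test <- function(correct_a, correct_b, exact_limit = 25) {
  stopifnot(is.logical(correct_a), is.logical(correct_b),
            length(correct_a) == length(correct_b))
  mcnemar_counts(
    b = sum(correct_a & !correct_b),
    c = sum(!correct_a & correct_b),
    exact_limit = exact_limit
  )
}

#' @rdname mcnemar_test
#' @param b,c Discordant counts (method A correct & B wrong; B correct & A
#'   wrong).
#' @export
mcnemar_counts <- function(b, c, exact_limit = 25) {
  n <- b + c
  if (n == 0) {
    return(tibble(b = 0L, c = 0L, statistic = 0, p_value = 1, method = "exact_binomial"))
  }
  if (n < exact_limit) {
    p <- binom.test(b, n, p = 0.5)$p.value
    tibble(b = as.integer(b), c = as.integer(c), statistic = NA_real_,
           p_value = p, method = "exact_binomial")
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    tibble(b = as.integer(b), c = as.integer(c), statistic = stat,
           p_value = pchisq(stat, df = 1, lower.tail = FALSE),
           method = "chi2_cc")
  }
}

#' Two-proportion chi-square test
#'
#' Compares two proportions (e.g. the fraction of cycles called biphasic by
#' each method) with the standard 2x2 chi-square, without continuity
#' correction by default.
#'
#' @param k1,n1,k2,n2 Successes and totals for the two groups.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return A one-row tibble: `p1`, `p2`, `statistic`, `p_value`. Degenerate
#'   margins (all successes pooled, or all failures) yield `NA` with a
#'   warning.
#' @export
proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 > 0, n2 > 0)
  p1 <- k1 / n1
  p2 <- k2 / n2
  if ((k1 + k2 == 0) || (k1 + k2 == n1 + n2)) {
    warn("Degenerate margin: proportion test undefined.")
    return(tibble(p1 = p1, p2 = p2, statistic = NA_real_, p_value = NA_real_))
  }
  pt <- suppressWarnings(
    prop.test(c(k1, k2), c(n1, n2), correct = correct)
  )
  tibble(p1 = p1, p2 = p2,
         statistic = unname(pt$statistic), p_value = pt$p.value)
}

#' Repeated-measures correlation
#'
#' Estimates the common within-subject (intraindividual) association between
#' two repeatedly measured variables via analysis of covariance with a
#' separate intercept per subject and one shared slope:
#' `y ~ subject + x`. The coefficient is
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))` with
#' `df = n_pairs - n_subjects - 1`; the p-value comes from the F test of the
#' shared slope and the 95% CI from the Fisher z transform.
#'
#' @param data A data frame of paired measurements.
#' @param subject,x,y Columns of `data`: subject identifier and the two
#'   measures (tidy-eval).
#' @return An `rmcorr_fit` object: `r_rm`, `df`, `ci_low`, `ci_high`,
#'   `p_value`, `slope`, `n_pairs`, `n_subjects`. Supports [tidy()] and
#'   [glance()].
#' @details Rows with a missing value in either measure are dropped.
#'   Subjects contribute within-subject information only if `x` varies for
#'   them; if `x` is constant within every subject the coefficient is
#'   undefined and an error is raised.
#' @export
rmcorr <- function(data, subject, x, y) {
  d <- tibble(
    subject = factor(dplyr::pull(data, {{ subject }})),
    x = dplyr::pull(data, {{ x }}),
    y = dplyr::pull(data, {{ y }})
  )
  d <- d[complete.cases(d), ]
  counts <- table(d$subject)
  counts <- counts[counts > 0]
  if (length(counts) < 2 || any(counts < 2)) {
    abort("rmcorr needs >= 2 subjects with >= 2 complete pairs each.",
      class = "ovushift_error_input"
    )
  }
  within_var <- tapply(d$x, d$subject, function(v) var(v) > 0)
  if (!any(within_var, na.rm = TRUE)) {
    abort("x is constant within every subject: no within-subject information.",
      class = "ovushift_error_degenerate"
    )
  }
  d$subject <- droplevels(d$subject)
  fit <- lm(y ~ subject + x, data = d)
  an <- anova(fit)
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df <- an["Residuals", "Df"]
  slope <- unname(coef(fit)["x"])
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  p <- pf(an["x", "F value"], 1, df, lower.tail = FALSE)
  # Fisher z interval using the ANCOVA error df in place of n - 3
  se_z <- 1 / sqrt(df - 1)
  z <- atanh(r)
  structure(
    list(
      r_rm = r, df = df,
      ci_low = tanh(z - qnorm(0.975) * se_z),
      ci_high = tanh(z + qnorm(0.975) * se_z),
      p_value = p, slope = slope,
      n_pairs = nrow(d), n_subjects = nlevels(d$subject)
    ),
    class = "rmcorr_fit"
  )
}

#' @export
print.rmcorr_fit <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures correlation: r_rm = %.3f (95%% CI %.3f to %.3f), df = %d, p = %.3g\n",
    x$r_rm, x$ci_low, x$ci_high, x$df, x$p_value
  ))
  invisible(x)
}

#' Evaluate one or two temperature methods against LH labels
#'
#' Convenience wrapper for the study-style report: per-method 2x2 tables and
#' accuracy metrics, the biphasic-rate comparison ([proportion_test()]), and
#' the paired accuracy comparison ([mcnemar_test()]) when two methods are
#' supplied.
#'
#' @param calls_list Named list of call tables (each with `cycle_id`,
#'   `status`), one per method.
#' @param labels Label table with `cycle_id`, `label`.
#' @return A list: `metrics` (named list of `diagnostic_report`s),
#'   `biphasic_rate` (tibble, one row per method), and for two methods
#'   `proportion_comparison` and `mcnemar` (one-row tibbles).
#' @export
evaluate_methods <- function(calls_list, labels) {
  stopifnot(is.list(calls_list), length(calls_list) >= 1, !is.null(names(calls_list)))
  metrics <- purrr::map(calls_list, ~ compute_metrics(build_contingency(.x, labels)))
  rates <- purrr::imap_dfr(calls_list, function(calls, nm) {
    tibble(method = nm, n = nrow(calls),
           n_biphasic = sum(calls$status == "biphasic"),
           pct_biphasic = 100 * mean(calls$status == "biphasic"))
  })
  out <- list(metrics = metrics, biphasic_rate = rates)
  if (length(calls_list) == 2) {
    a <- arrange(calls_list[[1]], .data$cycle_id)
    b <- arrange(calls_list[[2]], .data$cycle_id)
    lab <- arrange(labels, .data$cycle_id)
    stopifnot(identical(a$cycle_id, b$cycle_id), identical(a$cycle_id, lab$cycle_id))
    truth <- lab$label == "ovulatory"
    out$proportion_comparison <- proportion_test(
      rates$n_biphasic[1], rates$n[1], rates$n_biphasic[2], rates$n[2]
    )
    out$mcnemar <- mcnemar_test(
      (a$status == "biphasic") == truth,
      (b$status == "biphasic") == truth
    )
  }
  out
}
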