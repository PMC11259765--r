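# broom-style tidiers for the package's fitted objects

#' @rdname fit_thermal_coefficient
#' @param x A `thermal_model`.
#' @param ... Unused.
#' @method tidy thermal_model
#' @export
tidy.thermal_model <- function(x, ...) {
  tibble(term = c("k", "alpha"), estimate = c(x$k, x$alpha))
}

#' @rdname fit_thermal_coefficient
#' @method glance thermal_model
#' @export
glance.thermal_model <- function(x, ...) {
  tibble(
    k = x$k, alpha = x$alpha, n_points = x$n_points,
    residual_sd = x$residual_sd, clamped = x$clamped
  )
}

#' @rdname compute_metrics
#' @param x A `diagnostic_report`.
#' @param ... Unused.
#' @method tidy diagnostic_report
#' @export
tidy.diagnostic_report <- function(x, ...) {
  tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv", "f1"),
    value = c(x$sensitivity, x$specificity, x$ppv, x$npv, x$f1),
    unit = c(rep("percent", 4), "fraction")
  )
}

#' @rdname compute_metrics
#' @method glance diagnostic_report
#' @export
glance.diagnostic_report <- function(x, ...) {
  tibble(
    tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
    sensitivity = x$sensitivity, specificity = x$specificity,
    ppv = x$ppv, npv = x$npv, f1 = x$f1
  )
}

#' @rdname build_contingency
#' @param x An `ovu_contingency`.
#' @param ... Unused.
#' @method tidy ovu_contingency
#' @export
tidy.ovu_contingency <- function(x, ...) {
  tibble(
    cell = c("tp", "fp", "tn", "fn"),
    n = c(x$tp, x$fp, x$tn, x$fn)
  )
}

#' @rdname rmcorr
#' @param x An `rmcorr_fit`.
#' @param ... Unused.
#' @method tidy rmcorr_fit
#' @export
tidy.rmcorr_fit <- function(x, ...) {
  tibble(
    term = "r_rm", estimate = x$r_rm,
    conf.low = x$ci_low, conf.high = x$ci_high,
    df = x$df, p.value = x$p_value
  )
}

#' @rdname rmcorr
#' @method glance rmcorr_fit
#' @export
glance.rmcorr_fit <- function(x, ...) {
  tibble(
    r_rm = x$r_rm, df = x$df, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, slope = x$slope,
    n_pairs = x$n_pairs, n_subjects = x$n_subjects
  )
}
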