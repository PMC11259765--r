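# 2x2 metrics, paired McNemar, proportion test, repeated-measures correlation

test_that("contingency construction counts cells against the LH reference", {
  calls <- tibble::tibble(
    cycle_id = sprintf("c%02d", 1:6),
    status = c("biphasic", "biphasic", "monophasic", "monophasic", "biphasic", "monophasic")
  )
  labels <- tibble::tibble(
    cycle_id = sprintf("c%02d", 1:6),
    label = c("ovulatory", "anovulatory", "ovulatory", "anovulatory", "ovulatory", "anovulatory")
  )
  ct <- build_contingency(calls, labels)
  expect_identical(c(ct$tp, ct$fp, ct$tn, ct$fn), c(2L, 1L, 2L, 1L))
  expect_error(build_contingency(calls[0, ], labels[0, ]), class = "ovushift_error_input")
  expect_error(build_contingency(calls[1:3, ], labels), class = "ovushift_error_input")
})

test_that("diagnostic metrics match their defining ratios", {
  rep1 <- compute_metrics(contingency_table(tp = 51, fp = 1, tn = 13, fn = 9))
  expect_equal(rep1$sensitivity, 100 * 51 / 60)
  expect_equal(rep1$specificity, 100 * 13 / 14)
  expect_equal(rep1$ppv, 100 * 51 / 52)
  expect_equal(rep1$npv, 100 * 13 / 22)
  expect_equal(rep1$f1, 2 * 51 / (2 * 51 + 1 + 9))
  # a perfect classifier
  perfect <- compute_metrics(contingency_table(tp = 10, fp = 0, tn = 10, fn = 0))
  expect_equal(
    unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
    c(sensitivity = 100, specificity = 100, ppv = 100, npv = 100)
  )
  expect_equal(perfect$f1, 1)
  # undefined metrics stay NA without poisoning the rest
  noneg <- compute_metrics(contingency_table(tp = 5, fp = 2, tn = 0, fn = 0))
  expect_true(is.na(noneg$npv))
  expect_equal(noneg$sensitivity, 100)
  expect_s3_class(tidy(rep1), "tbl_df")
  expect_identical(nrow(glance(rep1)), 1L)
})

test_that("sensitivity/specificity swap under class relabelling and F1 is the harmonic mean", {
  withr::local_seed(17)
  for (i in 1:20) {
    n <- sample(1:30, 4, replace = TRUE)
    a <- compute_metrics(contingency_table(tp = n[1], fp = n[2], tn = n[3], fn = n[4]))
    b <- compute_metrics(contingency_table(tp = n[3], fp = n[4], tn = n[1], fn = n[2]))
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$specificity, b$sensitivity)
    if (!is.na(a$ppv) && !is.na(a$sensitivity) && (a$ppv + a$sensitivity) > 0) {
      h <- 2 / (100 / a$ppv + 100 / a$sensitivity)
      expect_equal(a$f1, h)
    }
  }
})

test_that("McNemar uses the exact binomial for small discordance", {
  expect_equal(mcnemar_counts(b = 0, c = 0)$p_value, 1)
  ex <- mcnemar_counts(b = 10, c = 0)
  expect_identical(ex$method, "exact_binomial")
  expect_equal(ex$p_value, 2 * 0.5^10)
})

test_that("McNemar switches to the continuity-corrected chi-square at 25 discordant", {
  cc <- mcnemar_counts(b = 15, c = 10)
  expect_identical(cc$method, "chi2_cc")
  expect_equal(cc$statistic, (abs(15 - 10) - 1)^2 / 25)
  # cross-check against the standard implementation
  ref <- stats::mcnemar.test(matrix(c(7, 15, 10, 7), 2), correct = TRUE)
  expect_equal(cc$statistic, unname(ref$statistic))
  expect_equal(cc$p_value, ref$p.value)
})

test_that("McNemar is symmetric in the two methods", {
  withr::local_seed(29)
  for (i in 1:10) {
    a <- runif(40) < 0.7
    b <- runif(40) < 0.6
    ab <- mcnemar_test(a, b)
    ba <- mcnemar_test(b, a)
    expect_identical(ab$b, ba$c)
    expect_equal(ab$p_value, ba$p_value)
  }
})

test_that("the proportion test matches the uncorrected chi-square", {
  res <- proportion_test(52, 74, 44, 74)
  expect_equal(res$p1, 52 / 74)
  expect_equal(res$p2, 44 / 74)
  ref <- stats::chisq.test(matrix(c(52, 74 - 52, 44, 74 - 44), 2, byrow = TRUE),
                           correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  # identical proportions: no signal
  same <- proportion_test(30, 60, 30, 60)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # maximal difference
  expect_lt(proportion_test(74, 74, 0, 74)$p_value, 1e-15)
  expect_warning(degen <- proportion_test(0, 10, 0, 10), "Degenerate")
  expect_true(is.na(degen$p_value))
})

rm_fixture <- function(n_subj, n_per, rho, seed) {
  withr::local_seed(seed)
  tibble::tibble(
    subject = rep(seq_len(n_subj), each = n_per),
    mu_x = rep(rnorm(n_subj, 0, 2), each = n_per),
    mu_y = rep(rnorm(n_subj, 0, 2), each = n_per),
    e = rnorm(n_subj * n_per)
  ) |>
    dplyr::mutate(
      x = mu_x + e,
      y = mu_y + rho * e + sqrt(1 - rho^2) * rnorm(n_subj * n_per)
    )
}

test_that("rmcorr recovers perfect and null within-subject relations", {
  d <- tibble::tibble(
    subject = rep(c("a", "b"), each = 5),
    x = c(1:5, 11:15),
    y = c(2 * (1:5) + 3, 2 * (11:15) - 40)
  )
  fit <- suppressWarnings(rmcorr(d, subject, x, y)) # noiseless: F test degenerate
  expect_equal(fit$r_rm, 1)
  expect_equal(fit$df, 10 - 2 - 1)
  null <- rm_fixture(20, 10, 0, seed = 101)
  fit0 <- rmcorr(null, subject, x, y)
  expect_lt(abs(fit0$r_rm), 0.15)
  expect_gt(fit0$p_value, 0.01)
})

test_that("rmcorr equals the correlation of within-subject-centred values", {
  d <- rm_fixture(12, 8, 0.6, seed = 55)
  fit <- rmcorr(d, subject, x, y)
  centred <- d |>
    dplyr::group_by(subject) |>
    dplyr::mutate(cx = x - mean(x), cy = y - mean(y)) |>
    dplyr::ungroup()
  expect_equal(fit$r_rm, stats::cor(centred$cx, centred$cy), tolerance = 1e-10)
})

test_that("rmcorr ignores per-subject location shifts", {
  d <- rm_fixture(10, 6, 0.5, seed = 77)
  fit <- rmcorr(d, subject, x, y)
  shifted <- d |>
    dplyr::group_by(subject) |>
    dplyr::mutate(x = x + 100 * dplyr::cur_group_id(),
                  y = y - 7 * dplyr::cur_group_id()) |>
    dplyr::ungroup()
  fit2 <- rmcorr(shifted, subject, x, y)
  expect_equal(fit$r_rm, fit2$r_rm, tolerance = 1e-10)
  expect_equal(fit$p_value, fit2$p_value, tolerance = 1e-10)
})

test_that("rmcorr rejects designs without within-subject information", {
  flat <- tibble::tibble(
    subject = rep(1:3, each = 3),
    x = rep(c(1, 2, 3), each = 3),
    y = rnorm(9)
  )
  expect_error(rmcorr(flat, subject, x, y), class = "ovushift_error_degenerate")
  tiny <- tibble::tibble(subject = 1:4, x = rnorm(4), y = rnorm(4))
  expect_error(rmcorr(tiny, subject, x, y), class = "ovushift_error_input")
})

test_that("rmcorr CIs cover a known generating correlation", {
  hits <- vapply(1:100, function(i) {
    d <- rm_fixture(20, 10, 0.6, seed = 2000 + i)
    fit <- rmcorr(d, subject, x, y)
    fit$ci_low <= 0.6 && 0.6 <= fit$ci_high
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})
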