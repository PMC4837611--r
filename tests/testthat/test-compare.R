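ev <- function(x, method = "lowback_accel") event_series(x, fs = 100, method = method)

test_that("event pairing counts steps and applies the stride fallback", {
  a <- ev(seq(100, 900, by = 100))                 # 9 events, 8 steps
  b <- ev(seq(102, 902, by = 100), "marker_reference")
  p <- pair_events(a, b)
  expect_equal(nrow(p), 8)
  expect_true(all(p$kind == "step"))

  # b missing event 4: steps (3,4) and (4,5) replaced by one stride (3,5)
  b4 <- ev(seq(102, 902, by = 100)[-4], "marker_reference")
  p4 <- pair_events(a, b4, missed_b = 4)
  expect_equal(nrow(p4), 7)
  expect_equal(sum(p4$kind == "stride"), 1)
  expect_equal(p4$a_ms[p4$kind == "stride"], 200 * 10)
  expect_equal(sum(p4$kind == "step"), 6)

  # all of b missing
  expect_error(pair_events(a, ev(integer(0), "marker_reference"), missed_b = 1:9),
               class = "stepmatch_pairing_error")
  # count mismatch is diagnosed
  expect_error(pair_events(a, b4, missed_b = integer(0)),
               class = "stepmatch_pairing_error")
})

test_that("pairing conserves the event span of both series", {
  set.seed(12)
  a_ev <- cumsum(c(100, round(rnorm(10, 56, 2))))
  b_ev <- a_ev + sample(-2:2, 11, replace = TRUE)
  missed <- c(4, 8)
  p <- pair_events(ev(a_ev), ev(b_ev[-missed], "marker_reference"), missed)
  expect_equal(sum(p$a_ms), (a_ev[11] - a_ev[1]) * 10)
  expect_equal(sum(p$b_ms), (b_ev[11] - b_ev[1]) * 10)
})

test_that("absolute differences, SD and percentage follow the definitions", {
  p <- pair_events(ev(c(0, 56, 112) + 100), ev(c(0, 54, 112) + 100, "marker_reference"))
  cmp <- absolute_differences(p)
  expect_equal(cmp$abs_diff_ms, c(20, 20))
  expect_equal(cmp$mean_abs_diff_ms, 20)
  expect_equal(cmp$sd_abs_diff_ms, 0)
  # pct uses the pooled mean step duration of both series
  expect_equal(cmp$pct_of_mean_step, 100 * 20 / mean(c(560, 560, 540, 580)))

  ident <- absolute_differences(pair_events(ev(c(100, 156, 212)),
                                            ev(c(100, 156, 212), "marker_reference")))
  expect_equal(ident$mean_abs_diff_ms, 0)
  expect_equal(ident$pct_of_mean_step, 0)

  single <- absolute_differences(pair_events(ev(c(100, 156)),
                                             ev(c(100, 158), "marker_reference")))
  expect_true(is.na(single$sd_abs_diff_ms))
})

test_that("absolute differences are symmetric in the two methods", {
  set.seed(3)
  a_ev <- cumsum(c(100, round(rnorm(9, 56, 3))))
  b_ev <- a_ev + sample(-3:3, 10, replace = TRUE)
  c1 <- absolute_differences(pair_events(ev(a_ev), ev(b_ev, "marker_reference")))
  c2 <- absolute_differences(pair_events(ev(b_ev), ev(a_ev, "marker_reference")))
  expect_equal(c1$abs_diff_ms, c2$abs_diff_ms)
  expect_equal(c1$pct_of_mean_step, c2$pct_of_mean_step)
})

test_that("ICC(2,1) matches the ANOVA oracle and its identities", {
  set.seed(41)
  for (i in 1:10) {
    a <- rnorm(15, 560, 20)
    b <- a + rnorm(15, 2, 8)
    expect_equal(icc_absolute_agreement(a, b), aov_icc21(a, b), tolerance = 1e-10)
    # symmetric in its arguments
    expect_equal(icc_absolute_agreement(a, b), icc_absolute_agreement(b, a),
                 tolerance = 1e-12)
  }
  x <- rnorm(20, 560, 25)
  expect_equal(icc_absolute_agreement(x, x), 1)
  # absolute agreement punishes a constant offset harder than Pearson r
  y <- x + 100
  expect_lt(icc_absolute_agreement(x, y), cor(x, y) - 0.3)
  expect_error(icc_absolute_agreement(rep(1, 5), rep(1, 5)),
               class = "stepmatch_degenerate_signal")
  expect_error(icc_absolute_agreement(1:2, 1:2), class = "stepmatch_invalid_input")
})

test_that("the normality gate selects the right paired test", {
  set.seed(51)
  picks <- replicate(400, {
    d <- rnorm(20, 0, 5)
    normality_gated_test(560 + d, rep(560, 20))$test_name
  })
  expect_gte(mean(picks == "paired t-test"), 0.90)

  picks_heavy <- replicate(200, {
    d <- rcauchy(20, 0, 5)
    normality_gated_test(560 + d, rep(560, 20))$test_name
  })
  expect_gt(mean(picks_heavy == "Wilcoxon signed-rank"), 0.5)

  # identical vectors: zero-variance convention
  same <- normality_gated_test(rep(5, 10), rep(5, 10))
  expect_equal(same$test_p, 1)
  expect_match(same$test_name, "degenerate")
})

test_that("compare_methods assembles the full comparison", {
  set.seed(61)
  a_ev <- cumsum(c(100, round(rnorm(12, 56, 2))))
  b_ev <- a_ev + sample(-2:2, 13, replace = TRUE)
  cmp <- compare_methods(ev(a_ev), ev(b_ev[-5], "marker_reference"), missed_b = 5)
  expect_s3_class(cmp, "method_comparison")
  expect_true(is.finite(cmp$icc))
  expect_true(cmp$test_name %in% c("paired t-test", "Wilcoxon signed-rank"))
  gl <- glance(cmp)
  expect_equal(gl$n_pairs, cmp$n_pairs)
  expect_equal(gl$n_stride_fallback, 1)
  td <- tidy(cmp)
  expect_equal(nrow(td), cmp$n_pairs)
  expect_equal(td$abs_diff_ms, abs(td$a_ms - td$b_ms))
})
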