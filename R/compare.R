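#' Pair durations between two event series
#'
#' Events of the two methods are matched by order over a shared episode.
#' Where method `b` missed an event (e.g. an occluded reference marker), the
#' two step durations adjacent to the gap cannot be formed; instead the
#' single stride duration spanning the gap is calculated in both series and
#' compared (the stride fallback). Gaps of more than one consecutive missed
#' event are dropped with a warning; a missed first or last event simply
#' drops the one adjacent pair.
#'
#' @param a An [event_series()] with one event per position of the shared
#'   grid (no misses).
#' @param b An [event_series()] whose events fill the grid positions not
#'   listed in `missed_b`.
#' @param missed_b Integer ordinal positions (into the grid of `a`) at which
#'   `b` has no event.
#' @return A tibble of class `"paired_durations"` with columns `a_ms`,
#'   `b_ms`, `kind` (`"step"` or `"stride"`), and attributes `methods`, `fs`.
#' @export
pair_events <- function(a, b, missed_b = integer(0)) {
  fs_a <- attr(a, "fs"); fs_b <- attr(b, "fs")
  if (!isTRUE(all.equal(fs_a, fs_b))) {
    abort_stage("event series have different sampling rates", "stepmatch_pairing_error")
  }
  n <- nrow(a)
  missed_b <- sort(unique(as.integer(missed_b)))
  if (length(missed_b) > 0 && (min(missed_b) < 1 || max(missed_b) > n)) {
    abort_stage("missed positions outside the event grid", "stepmatch_pairing_error")
  }
  present <- setdiff(seq_len(n), missed_b)
  if (length(present) < 2) {
    abort_stage(sprintf(
      "cannot pair events: %d of %d grid positions present in the second series\n  a: %s\n  b: %s",
      length(present), n, paste(utils::head(a$event, 10), collapse = ","),
      paste(utils::head(b$event, 10), collapse = ",")), "stepmatch_pairing_error")
  }
  if (nrow(b) != length(present)) {
    abort_stage(sprintf(
      "event count mismatch: second series has %d events for %d non-missed grid positions\n  a: %s\n  b: %s",
      nrow(b), length(present), paste(utils::head(a$event, 10), collapse = ","),
      paste(utils::head(b$event, 10), collapse = ",")), "stepmatch_pairing_error")
  }
  b_full <- rep(NA_integer_, n)
  b_full[present] <- b$event
  a_ms <- b_ms <- numeric(0)
  kind <- character(0)
  dropped <- 0L
  for (j in seq_len(length(present) - 1)) {
    i1 <- present[j]; i2 <- present[j + 1]
    gap <- i2 - i1
    if (gap > 2) {
      dropped <- dropped + 1L
      next
    }
    a_ms <- c(a_ms, (a$event[i2] - a$event[i1]) * 1000 / fs_a)
    b_ms <- c(b_ms, (b_full[i2] - b_full[i1]) * 1000 / fs_b)
    kind <- c(kind, if (gap == 1) "step" else "stride")
  }
  if (dropped > 0) {
    rlang::warn(sprintf("%d interval(s) spanning >1 missed event dropped", dropped))
  }
  if (length(a_ms) == 0) {
    abort_stage("no comparable duration pairs remain", "stepmatch_pairing_error")
  }
  out <- tibble::tibble(a_ms = a_ms, b_ms = b_ms, kind = kind)
  attr(out, "methods") <- c(attr(a, "method") %||% "a", attr(b, "method") %||% "b")
  attr(out, "fs") <- fs_a
  class(out) <- c("paired_durations", class(out))
  out
}

#' Absolute duration differences between two methods
#'
#' Per-pair absolute differences in milliseconds, their mean and sample
#' standard deviation, and the mean expressed as a percentage of the mean
#' step duration pooled over both series (stride-fallback entries contribute
#' half their duration to the pooled mean, so the denominator stays on the
#' step scale).
#'
#' @param paired A [pair_events()] result.
#' @return A list of class `"method_comparison"`: `pairs`, `abs_diff_ms`,
#'   `mean_abs_diff_ms`, `sd_abs_diff_ms` (`NA` for a single pair),
#'   `pct_of_mean_step`, `n_pairs`, `methods`. ICC and test fields are `NA`
#'   until filled by [compare_methods()].
#' @export
absolute_differences <- function(paired) {
  stopifnot(inherits(paired, "paired_durations"))
  d <- abs(paired$a_ms - paired$b_ms)
  pooled <- c(paired$a_ms, paired$b_ms) /
    rep(ifelse(paired$kind == "stride", 2, 1), 2)
  mean_abs <- mean(d)
  structure(list(
    pairs = paired,
    abs_diff_ms = d,
    mean_abs_diff_ms = mean_abs,
    sd_abs_diff_ms = if (length(d) > 1) stats::sd(d) else NA_real_,
    pct_of_mean_step = 100 * mean_abs / mean(pooled),
    n_pairs = length(d),
    methods = attr(paired, "methods"),
    icc = NA_real_, normality_p = NA_real_,
    test_name = NA_character_, test_p = NA_real_, alpha = 0.05
  ), class = "method_comparison")
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation (Shrout-Fleiss ICC(2,1)) between two paired measurement
#' series, computed from the ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with `k = 2` raters
#' and `n` paired observations.
#'
#' @param a,b Equal-length numeric vectors (n >= 3) of paired measurements.
#' @return ICC in `[-1, 1]`.
#' @export
icc_absolute_agreement <- function(a, b) {
  a <- as.double(a); b <- as.double(b)
  n <- length(a)
  if (length(b) != n || n < 3) {
    abort_stage("ICC needs two equal-length vectors with n >= 3",
                "stepmatch_invalid_input")
  }
  k <- 2
  y <- c(a, b)
  grand <- mean(y)
  row_means <- (a + b) / 2
  col_means <- c(mean(a), mean(b))
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * 100 * max(1, abs(msr))) {
    abort_stage("zero total variance; ICC undefined", "stepmatch_degenerate_signal")
  }
  (msr - mse) / denom
}

#' Normality-gated paired comparison test
#'
#' Shapiro-Wilk is applied to the paired differences; when it does not
#' reject normality (p > alpha) a paired t-test is used, otherwise a
#' Wilcoxon signed-rank test. Identical inputs (all differences zero) are
#' reported with p = 1 under the zero-variance convention.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return A list: `test_name`, `test_p`, `normality_p`.
#' @export
normality_gated_test <- function(x, y, alpha = 0.05) {
  x <- as.double(x); y <- as.double(y)
  if (length(x) != length(y) || length(x) < 3) {
    abort_stage("paired test needs equal-length vectors with n >= 3",
                "stepmatch_invalid_input")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(test_name = "paired t-test (degenerate: zero variance)",
                test_p = 1, normality_p = NA_real_))
  }
  norm_p <- stats::shapiro.test(d)$p.value
  if (norm_p > alpha) {
    tt <- stats::t.test(x, y, paired = TRUE)
    list(test_name = "paired t-test", test_p = tt$p.value, normality_p = norm_p)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = FALSE))
    list(test_name = "Wilcoxon signed-rank", test_p = wt$p.value,
         normality_p = norm_p)
  }
}

#' Full between-method comparison
#'
#' Pairs the two event series (with the stride fallback for missed events),
#' computes absolute duration differences, the ICC(2,1) of the paired
#' durations, and the normality-gated paired test.
#'
#' @inheritParams pair_events
#' @param alpha Significance level (default 0.05).
#' @return A `"method_comparison"` object, see [absolute_differences()].
#' @export
compare_methods <- function(a, b, missed_b = integer(0), alpha = 0.05) {
  paired <- pair_events(a, b, missed_b)
  cmp <- absolute_differences(paired)
  cmp$alpha <- alpha
  if (cmp$n_pairs >= 3) {
    cmp$icc <- tryCatch(icc_absolute_agreement(paired$a_ms, paired$b_ms),
                        stepmatch_error = function(e) NA_real_)
    gt <- normality_gated_test(paired$a_ms, paired$b_ms, alpha)
    cmp$normality_p <- gt$normality_p
    cmp$test_name <- gt$test_name
    cmp$test_p <- gt$test_p
  }
  cmp
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %s vs %s, %d pairs\n",
              x$methods[1], x$methods[2], x$n_pairs))
  cat(sprintf("  mean |diff| %.1f +/- %.1f ms (%.1f%% of mean step duration)\n",
              x$mean_abs_diff_ms, x$sd_abs_diff_ms, x$pct_of_mean_step))
  if (is.finite(x$icc)) cat(sprintf("  ICC(2,1) = %.3f\n", x$icc))
  if (!is.na(x$test_name)) {
    cat(sprintf("  %s p = %.3g (Shapiro-Wilk p = %.3g, alpha = %.2f)\n",
                x$test_name, x$test_p, x$normality_p, x$alpha))
  }
  invisible(x)
}

#' Tidy per-pair comparison rows
#'
#' @param x A `"method_comparison"`.
#' @param ... Unused.
#' @return A tibble with one row per duration pair: `pair`, `a_ms`, `b_ms`,
#'   `kind`, `abs_diff_ms`.
#' @export
tidy.method_comparison <- function(x, ...) {
  tibble::tibble(
    pair = seq_len(x$n_pairs),
    a_ms = x$pairs$a_ms,
    b_ms = x$pairs$b_ms,
    kind = x$pairs$kind,
    abs_diff_ms = x$abs_diff_ms
  )
}

#' One-row comparison summary
#'
#' @param x A `"method_comparison"`.
#' @param ... Unused.
#' @return A one-row tibble with the summary statistics of the comparison.
#' @export
glance.method_comparison <- function(x, ...) {
  tibble::tibble(
    method_a = x$methods[1], method_b = x$methods[2],
    n_pairs = x$n_pairs,
    n_stride_fallback = sum(x$pairs$kind == "stride"),
    mean_abs_diff_ms = x$mean_abs_diff_ms,
    sd_abs_diff_ms = x$sd_abs_diff_ms,
    pct_of_mean_step = x$pct_of_mean_step,
    icc = x$icc,
    normality_p = x$normality_p,
    test_name = x$test_name,
    test_p = x$test_p
  )
}
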