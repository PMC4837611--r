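sinusoid_trace <- function(freq, fs = 100, secs = 10) {
  accel_trace(sin(2 * pi * freq * (0:(fs * secs - 1)) / fs), fs = fs)
}

test_that("lower-back template length is fs over the dominant frequency", {
  expect_equal(template_length_lowback(sinusoid_trace(2.0))$tl, 50)
  expect_equal(template_length_lowback(sinusoid_trace(1.25))$tl, 80)
  expect_equal(template_length_lowback(sinusoid_trace(1.79))$tl, 56)  # round(55.87)
})

test_that("lower-back template length recovers integer periods exactly or within 1", {
  for (p in c(40, 50, 56, 80)) {
    x <- rep(sin(2 * pi * (0:(p - 1)) / p), length.out = 1200)
    tl <- template_length_lowback(accel_trace(x, fs = 100))$tl
    expect_lte(abs(tl - p), 1)
  }
})

test_that("heel template length reads the stride lag off the autocovariance", {
  tr <- generate_trial(gait_params(n_steps = 10, step_cv = 0, asymmetry = 0,
                                   noise_sd = 0, seed = 3))
  seg <- segment_trace(tr$heel_left, tr$window)
  tl <- template_length_heel(seg)
  expect_lte(abs(tl$tl - 112), 2)  # stride = 2 x 56 samples
  # normalized autocovariance is exactly 1 at lag 0
  a <- unbiased_autocovariance(seg)
  expect_equal(a$acov[1] / a$acov[1], 1.0)
})

test_that("heel template length is about twice the lower-back template length", {
  tr <- generate_trial(gait_params(n_steps = 10, step_cv = 0.02, asymmetry = 0.02,
                                   noise_sd = 0, seed = 11))
  tl_lb <- template_length_lowback(segment_trace(tr$lowback, tr$window))
  tl_h <- template_length_heel(segment_trace(tr$heel_left, tr$window))
  expect_lt(abs(tl_h$tl - 2 * tl_lb$tl) / (2 * tl_lb$tl), 0.10)
})

test_that("white noise raises a periodicity-not-found error for heel TL", {
  set.seed(5)
  expect_error(template_length_heel(accel_trace(rnorm(800), fs = 100,
                                                placement = "heel_left")),
               class = "stepmatch_degenerate_signal")
})

test_that("anchor peaks respect limits, spacing and the greedy order", {
  # maxima every 50 samples, tl = 50, n = 500: admissible band excludes
  # round(1.15 * 50) = 58 samples at both ends
  x <- rep(0, 500)
  x[seq(50, 450, by = 50)] <- 1
  x <- x + 0.001 * sin(seq_len(500))  # break exact ties, keep maxima at spikes
  peaks <- find_template_peaks(accel_trace(x, fs = 100), 50)
  expect_true(all(peaks %in% seq(100, 400, by = 50)))
  expect_true(all(diff(peaks) >= 20))
  expect_gte(min(peaks), 59)
  expect_lte(max(peaks), 500 - 58)

  # two equal-height maxima 10 samples apart: greedy keeps only one
  y <- rep(0, 500)
  y[c(200, 210)] <- 1
  y[c(120, 320, 400)] <- 0.9
  py <- find_template_peaks(accel_trace(y + 1e-4 * cos(seq_len(500)), fs = 100), 50,
                            detector_config(peak_min_height_frac = 0))
  expect_equal(sum(py %in% c(200, 210)), 1)
  expect_equal(py[py %in% c(200, 210)], 200)  # earlier index wins the tie

  # fewer than two admissible peaks
  expect_error(find_template_peaks(accel_trace(c(rep(0, 240), 1, rep(0, 259)),
                                               fs = 100), 50),
               class = "stepmatch_too_few_cycles")
})

test_that("sections are anchored with the pre-peak margin and fixed length", {
  seg <- accel_trace(seq_len(300) / 300, fs = 100)
  # peak 100, tl 50, pre 0.15: starts round(7.5) = 8 samples before the peak
  s <- extract_sections(seg, c(100, 200), 50, pre_fraction = 0.15)
  expect_length(s, 2)
  expect_length(s[[1]], 58)
  expect_equal(s[[1]], seg$accel[92:149])
  # pre 0.05 with tl 100 gives length 105
  s2 <- extract_sections(seg, c(100, 200), 100, pre_fraction = 0.05)
  expect_length(s2[[1]], 105)
  expect_equal(s2[[1]], seg$accel[95:199])
  # a peak too close to the boundary is dropped with a warning
  expect_warning(s3 <- extract_sections(seg, c(3, 100, 200), 50, 0.15),
                 regexp = "dropped")
  expect_length(s3, 2)
  expect_error(suppressWarnings(extract_sections(seg, c(3, 299), 50, 0.15)),
               class = "stepmatch_too_few_cycles")
})

test_that("DTW alignment cost matches exhaustive path enumeration", {
  expect_equal(dtw_align(c(0, 0, 1, 0, 0), c(0, 1, 0, 0, 0))$cost,
               brute_dtw_cost(c(0, 0, 1, 0, 0), c(0, 1, 0, 0, 0)))
  set.seed(21)
  for (i in 1:12) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    a <- round(rnorm(n), 2); b <- round(rnorm(m), 2)
    expect_equal(dtw_align(a, b)$cost, brute_dtw_cost(a, b), tolerance = 1e-12)
  }
})

test_that("DTW averaging is the identity on equal or constant inputs", {
  a <- sin(1:30 / 3)
  expect_equal(dtw_average_pair(a, a), a)
  expect_equal(dtw_average_pair(rep(2, 10), rep(2, 10)), rep(2, 10))
  expect_error(dtw_align(numeric(0), 1:3), class = "stepmatch_invalid_input")
})

test_that("templates average out small phase jitter", {
  set.seed(9)
  cycle <- sin(2 * pi * (0:63) / 64)
  sections <- lapply(c(-2, 1, 0, 2), function(sh) {
    sin(2 * pi * ((0:63) + sh) / 64) + rnorm(64, 0, 0.01)
  })
  tpl <- build_template(sections, 64, pre_fraction = 0)
  expect_length(tpl$values, 64)
  expect_gt(cor(tpl$values, cycle), 0.99)
})

test_that("templates are exact for identical sections and invariant to duplication", {
  sec <- cos(2 * pi * (0:57) / 58)
  tpl2 <- build_template(list(sec, sec), 50, pre_fraction = 0.15)
  expect_length(tpl2$values, 50)
  expect_equal(tpl2$values, sec[1:50])
  sections <- lapply(1:4, function(i) sin(2 * pi * ((0:57) + i) / 58))
  t1 <- build_template(sections, 50)
  t2 <- build_template(c(sections, sections), 50)
  expect_equal(t1$values, t2$values, tolerance = 1e-12)
})
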