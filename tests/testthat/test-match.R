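test_that("resegmentation extends by TL left and twice TL right", {
  tr <- accel_trace(rnorm(1000), fs = 100)
  rs <- resegment(tr, seg_window(101, 600), 50)
  expect_equal(rs$window$start, 51)
  expect_equal(rs$window$end, 700)
  expect_equal(nrow(rs$trace), 650)
  expect_equal(rs$trace$sample[1], 51)
  expect_error(resegment(tr, seg_window(31, 600), 50),
               class = "stepmatch_resegment_error")
  expect_error(resegment(tr, seg_window(101, 950), 50),
               class = "stepmatch_resegment_error")
  expect_error(resegment(tr, seg_window(101, 600), 0),
               class = "stepmatch_invalid_input")
})

test_that("SD-difference signal matches the naive per-window loop", {
  set.seed(31)
  x <- rnorm(400)
  tpl <- rnorm(40)
  got <- sd_difference_signal(x, tpl)
  ref <- naive_sd_diff(x, tpl)
  expect_length(got, 400 - 40 + 1)
  expect_equal(got, ref / max(ref), tolerance = 1e-10)
})

test_that("SD difference is zero at exact and shifted copies of the template", {
  set.seed(32)
  tpl <- rnorm(30)
  x <- c(rnorm(50), tpl, rnorm(40), tpl + 5, rnorm(50))
  s <- sd_difference_signal(x, tpl)
  expect_equal(s[51], 0)        # exact embedded copy
  expect_equal(s[121], 0)       # amplitude shift is invisible to the SD
  expect_error(sd_difference_signal(rep(1, 100), rep(1, 10)),
               class = "stepmatch_degenerate_match")
})

test_that("correlation signal matches the naive loop and the range-ratio rule", {
  set.seed(33)
  x <- rnorm(300)
  tpl <- rnorm(25)
  got <- correlation_signal(x, tpl)
  ref <- naive_corr(x, tpl)
  expect_equal(got, ref / max(ref), tolerance = 1e-10)

  # un-normalized values at constructed windows
  x2 <- c(rnorm(40), tpl, rnorm(10), 2 * tpl, rnorm(10), -tpl, rnorm(40))
  raw <- naive_corr(x2, tpl)
  expect_equal(raw[41], 1)          # identical window: corr 1, ratio 1
  expect_equal(raw[76], 0.5)        # doubled window: corr 1, min(2, 1/2)
  expect_equal(raw[111], -1)        # negated window: corr -1, ratio 1
  # constant windows get correlation 0
  x3 <- c(rep(0, 30), tpl, rnorm(30))
  expect_equal(correlation_signal(x3, tpl)[1], 0)
})

test_that("coefficient signal floors the denominator and peaks at exact matches", {
  set.seed(34)
  tpl <- rnorm(30)
  x <- c(rnorm(60), tpl, rnorm(60))
  sd_sig <- sd_difference_signal(x, tpl)
  corr_sig <- correlation_signal(x, tpl)
  coeff <- coefficient_signal(corr_sig, sd_sig)
  expect_length(coeff, length(sd_sig))
  expect_equal(which.max(coeff), 61)  # the embedded copy dominates
  expect_true(all(coeff[corr_sig <= 0] <= 0))  # sign propagates
  expect_error(coefficient_signal(corr_sig, sd_sig[-1]),
               class = "stepmatch_invalid_input")
})

test_that("event peaks are selected greedily then filtered to the segment", {
  # peaks of descending height every 40 samples; tl = 50 -> min distance 30
  coeff <- rep(0, 200)
  coeff[c(20, 60, 100, 140, 180)] <- c(5, 4, 3, 2, 1)
  win <- seg_window(30, 170)
  got <- select_event_peaks(coeff, 50, win, offset = 1, shift_fraction = 0.15)
  expect_equal(got, c(60, 100, 140))  # 20 and 180 fall outside the segment

  # peaks closer than 60 % TL are suppressed in favour of the higher one
  coeff2 <- rep(0, 200)
  coeff2[c(100, 120)] <- c(3, 2.9)
  got2 <- select_event_peaks(coeff2, 50, seg_window(10, 190), 1, 0.15)
  expect_equal(got2, 100)
  # at exactly the minimum distance both survive
  coeff3 <- rep(0, 200)
  coeff3[c(100, 130)] <- c(3, 2.9)
  got3 <- select_event_peaks(coeff3, 50, seg_window(10, 190), 1, 0.15)
  expect_equal(got3, c(100, 130))

  # strictly monotone signal has no interior maxima
  expect_error(select_event_peaks(seq_len(100) / 100, 50, seg_window(10, 90), 1, 0.15),
               class = "stepmatch_no_steps")
})

test_that("events are shifted forward by the pre-fraction of TL", {
  ev <- shift_events(c(20, 76), 50, 0.15, fs = 100)
  expect_equal(ev$event, c(28, 84))  # round(7.5) = 8, half away from zero
  ev2 <- shift_events(c(20, 76), 100, 0.05, fs = 100)
  expect_equal(ev2$event, c(25, 81))
  expect_equal(nrow(shift_events(integer(0), 50, 0.15, fs = 100)), 0)
})

test_that("durations are inter-event intervals in milliseconds", {
  ev <- event_series(c(28, 84, 140), fs = 100)
  expect_equal(durations_from_events(ev)$duration_ms, c(560, 560))
  expect_equal(durations_from_events(event_series(c(1, 101), fs = 100))$duration_ms, 1000)
  expect_error(durations_from_events(event_series(42, fs = 100)),
               class = "stepmatch_invalid_input")
})

test_that("heel event series combine only when feet alternate", {
  left <- event_series(c(100, 212), fs = 100, method = "heel_accel_left")
  right <- event_series(c(156, 270), fs = 100, method = "heel_accel_right")
  comb <- combine_heel_events(left, right)
  expect_equal(comb$event, c(100, 156, 212, 270))
  expect_equal(comb$foot, c("left", "right", "left", "right"))
  expect_equal(durations_from_events(comb, "step")$duration_ms, c(560, 560, 580))

  one <- event_series(100, fs = 100, method = "heel_accel_left")
  two <- event_series(c(50, 156), fs = 100, method = "heel_accel_right")
  expect_equal(combine_heel_events(one, two)$event, c(50, 100, 156))

  bad_l <- event_series(c(100, 150), fs = 100, method = "heel_accel_left")
  bad_r <- event_series(300, fs = 100, method = "heel_accel_right")
  expect_error(combine_heel_events(bad_l, bad_r),
               class = "stepmatch_interleaving_error")
})

test_that("event series must be strictly increasing", {
  expect_error(event_series(c(10, 10, 20), fs = 100),
               class = "stepmatch_invalid_input")
})
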