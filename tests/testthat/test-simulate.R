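test_that("trials are deterministic given the seed", {
  p <- gait_params(n_steps = 8, step_cv = 0.02, asymmetry = 0.03,
                   snr_db = 15, dropout = 0.001, seed = 77)
  t1 <- generate_trial(p)
  t2 <- generate_trial(p)
  expect_identical(t1$lowback$accel, t2$lowback$accel)
  expect_identical(t1$heel_left$accel, t2$heel_left$accel)
  expect_identical(t1$markers$heel_left[[2]]$visible,
                   t2$markers$heel_left[[2]]$visible)
  expect_identical(t1$truth, t2$truth)
  t3 <- generate_trial(gait_params(n_steps = 8, step_cv = 0.02, asymmetry = 0.03,
                                   snr_db = 15, dropout = 0.001, seed = 78))
  expect_false(identical(t1$lowback$accel, t3$lowback$accel))
})

test_that("zero variability gives exactly the mean step duration", {
  tr <- generate_trial(gait_params(n_steps = 8, step_cv = 0, asymmetry = 0,
                                   noise_sd = 0, seed = 1))
  expect_equal(diff(tr$truth$event), rep(56, 8))
  # sum of step durations equals the full first-to-last interval
  expect_equal(sum(diff(tr$truth$event)),
               tr$truth$event[9] - tr$truth$event[1])
})

test_that("asymmetry separates left and right step durations, not strides", {
  tr <- generate_trial(gait_params(n_steps = 12, step_cv = 0, asymmetry = 0.05,
                                   noise_sd = 0, seed = 2))
  steps <- diff(tr$truth$event) * 10
  lead <- tr$truth$side[-1]
  expect_equal(mean(steps[lead == "left"]) - mean(steps[lead == "right"]),
               0.05 * 560, tolerance = 10)  # one-sample rounding
  strides_l <- diff(tr$truth_left) * 10
  strides_r <- diff(tr$truth_right) * 10
  expect_equal(mean(strides_l), mean(strides_r), tolerance = 10)
})

test_that("ground truth alternates feet and is strictly increasing", {
  tr <- generate_trial(gait_params(n_steps = 11, step_cv = 0.03, seed = 5))
  expect_true(all(diff(tr$truth$event) > 0))
  expect_true(all(tr$truth$side[-1] != tr$truth$side[-nrow(tr$truth)]))
})

test_that("noiseless waveforms are periodic with the construction period", {
  tr <- generate_trial(gait_params(n_steps = 10, step_cv = 0, asymmetry = 0,
                                   noise_sd = 0, seed = 3))
  x <- tr$heel_left$accel
  s <- tr$truth_left
  # stride-periodic to machine precision over interior strikes
  i1 <- s[2]:(s[2] + 80); i2 <- s[3]:(s[3] + 80)
  expect_equal(x[i1], x[i2], tolerance = 1e-9)
  # heel spike maxima sit on the ground-truth strikes
  expect_equal(which.max(x[(s[2] - 10):(s[2] + 10)]), 11)
  # lower-back dominant frequency matches the step rate
  seg <- segment_trace(tr$lowback, tr$window)
  f <- dominant_frequency(unbiased_autocovariance(seg), 100)
  expect_equal(f, 1000 / 560, tolerance = 0.05)
})

test_that("snr_db calibrates the realized in-segment SNR", {
  p <- gait_params(n_steps = 10, step_cv = 0, asymmetry = 0, snr_db = 10, seed = 4)
  tr <- generate_trial(p)
  clean <- generate_trial(gait_params(n_steps = 10, step_cv = 0, asymmetry = 0,
                                      noise_sd = 0, seed = 4))
  seg <- tr$window$start:tr$window$end
  noise <- tr$lowback$accel[seg] - clean$lowback$accel[seg]
  snr <- 10 * log10(var(clean$lowback$accel[seg]) / var(noise))
  expect_equal(snr, 10, tolerance = 1)
})

test_that("doubling the waveform amplitude leaves detected events unchanged", {
  tr <- generate_trial(gait_params(n_steps = 8, step_cv = 0.02, noise_sd = 0,
                                   seed = 6))
  base <- detect_steps_lowback(tr$lowback, tr$window)$events$event
  doubled <- accel_trace(2 * tr$lowback$accel, fs = 100, placement = "lower_back")
  expect_equal(detect_steps_lowback(doubled, tr$window)$events$event, base)
})

test_that("marker trajectories peak at the ground-truth strikes", {
  tr <- generate_trial(gait_params(n_steps = 9, step_cv = 0.02, noise_sd = 0,
                                   seed = 7))
  heel <- resample_to(tr$markers$heel_left[[2]], 100)
  back <- resample_to(tr$markers$back[[1]], 100)
  d <- heel$ap - back$ap
  for (s in tr$truth_left) {
    local_max <- which.max(d[(s - 15):(s + 15)]) + s - 16
    expect_lte(abs(local_max - s), 1)
  }
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(gait_params(n_steps = 3), class = "stepmatch_invalid_params")
  expect_error(gait_params(mean_step_ms = 150), class = "stepmatch_invalid_params")
  expect_error(gait_params(step_cv = 0.5), class = "stepmatch_invalid_params")
  expect_error(gait_params(dropout = 1.5), class = "stepmatch_invalid_params")
})
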