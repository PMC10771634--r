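analytic_gain <- function(f_hz, order = 6, cutoff = 3, fs = 20) {
  # squared magnitude of the digital Butterworth design applied forward and
  # backward (bilinear transform prewarps the frequency axis)
  r <- tan(pi * f_hz / fs) / tan(pi * cutoff / fs)
  1 / (1 + r^(2 * order))
}

sine_amplitude <- function(x) {
  # amplitude of a zero-mean sinusoid from its RMS over whole periods
  sqrt(2 * mean((x - mean(x))^2))
}

test_that("the zero-phase filter has unit DC gain and is linear", {
  spec <- filter_spec()
  x <- rep(0.73, 200)
  expect_lt(max(abs(lowpass_filter(x, spec) - 0.73)), 1e-9)

  set.seed(4)
  a <- rnorm(300); b <- rnorm(300)
  lhs <- lowpass_filter(2.5 * a - 1.3 * b, spec)
  rhs <- 2.5 * lowpass_filter(a, spec) - 1.3 * lowpass_filter(b, spec)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("the filter's frequency response matches the analytic form", {
  spec <- filter_spec()
  t <- (0:799) / 20
  # passband: 0.5 Hz
  y <- lowpass_filter(sin(2 * pi * 0.5 * t), spec)
  got <- sine_amplitude(y[101:700])
  expect_lt(abs(got - analytic_gain(0.5)) / analytic_gain(0.5), 0.02)
  # well above cutoff: 8 Hz is annihilated
  y8 <- lowpass_filter(sin(2 * pi * 8 * t), spec)
  expect_lt(max(abs(y8[101:700])), 0.01)
  # intermediate frequency, amplitude still tracks the analytic response
  y2 <- lowpass_filter(sin(2 * pi * 2 * t), spec)
  expect_lt(abs(sine_amplitude(y2[101:700]) - analytic_gain(2)) /
              analytic_gain(2), 0.02)
})

test_that("the filter is zero-phase on band-limited input", {
  t <- (0:599) / 20
  x <- sin(2 * pi * 0.8 * t) + 0.5 * cos(2 * pi * 1.7 * t)
  y <- lowpass_filter(x, filter_spec())
  cc <- ccf(x, y, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filter parameter and length contracts are enforced", {
  expect_error(filter_spec(cutoff_hz = 10, frame_rate_hz = 20),
               class = "tug_parameter_error")
  expect_error(filter_spec(cutoff_hz = 0), class = "tug_parameter_error")
  expect_error(filter_spec(order = 0), class = "tug_parameter_error")
  expect_error(lowpass_filter(rnorm(10), filter_spec()),
               class = "tug_length_error")
})

test_that("filtering a recording preserves band-limited motion, cuts noise", {
  clean <- generate_recording(tug_profile(noise_sd_m = 0), seed = 6)$recording
  fclean <- filter_recording(clean)
  # generator motion is essentially sub-3 Hz: sub-millimeter agreement away
  # from movement corners, bounded corner rounding where the acceleration
  # steps put energy above the cutoff
  resid <- abs(fclean$xyz - clean$xyz)
  expect_lt(stats::quantile(resid, 0.90), 2e-3)
  expect_lt(max(resid), 0.025)
  expect_identical(fclean$subject, clean$subject)

  noisy <- generate_recording(tug_profile(noise_sd_m = 0.005), seed = 6)$recording
  fnoisy <- filter_recording(noisy)
  resid_in <- noisy$xyz - clean$xyz
  resid_out <- fnoisy$xyz - clean$xyz
  expect_lt(mean(resid_out^2), 0.8 * mean(resid_in^2))

  one <- crop_recording(clean, 1)
  expect_error(filter_recording(one), class = "tug_length_error")
})

test_that("quality screening flags injected spikes and nothing else", {
  rec <- default_sim()$rec
  qc <- screen_quality(rec, 3)
  expect_true(qc$pass)
  expect_equal(nrow(qc$offending_intervals), 0)

  spiked <- rec
  spiked$xyz[200, "AnkleRight", "z"] <- spiked$xyz[200, "AnkleRight", "z"] + 0.5
  qc2 <- screen_quality(spiked, 3)
  expect_false(qc2$pass)
  expect_true(any(qc2$offending_intervals$start_frame <= 199 &
                    qc2$offending_intervals$end_frame >= 199))
  expect_gt(qc2$max_jump_mps, 3)
  # pass is definitionally the absence of offending intervals
  expect_identical(qc2$pass, nrow(qc2$offending_intervals) == 0)
})

test_that("screening is invariant to rigid translation of the recording", {
  rec <- default_sim()$rec
  shifted <- rec
  shifted$xyz <- shifted$xyz + 0.35
  a <- screen_quality(rec, 3)
  b <- screen_quality(shifted, 3)
  expect_identical(a$pass, b$pass)
  expect_equal(a$max_jump_mps, b$max_jump_mps, tolerance = 1e-9)
})
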