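test_that("artifact filtering interpolates out-of-range readings", {
  expect_equal(filter_hr_artifacts(trace(c(600, 150, 600), 1))$values,
               c(600, 600, 600))
  expect_equal(filter_hr_artifacts(trace(c(400, 900, 500), 1))$values,
               c(400, 450, 500))
  # boundary values 200 and 800 are retained (the rule is strict < / >)
  expect_equal(filter_hr_artifacts(trace(rep(200, 5), 1))$values, rep(200, 5))
  expect_equal(filter_hr_artifacts(trace(c(300, 800, 300), 1))$values,
               c(300, 800, 300))
  # leading/trailing invalid runs take the nearest valid value
  expect_equal(filter_hr_artifacts(trace(c(150, 150, 600, 900), 1))$values,
               c(600, 600, 600, 600))
  expect_error(filter_hr_artifacts(trace(c(150, 900), 1)), "no valid")
})

test_that("beat intervals are the reciprocal of heart rate", {
  expect_equal(to_beat_interval(trace(600, 1))$values, 0.1)
  expect_equal(to_beat_interval(trace(200, 1))$values, 0.3)
  hr <- sine_trace(0.5, 20, 10, amp = 30, offset = 600)
  iv <- to_beat_interval(hr)
  expect_equal(iv$values, 60 / hr$values)
  expect_equal(iv$rate, hr$rate)
  expect_error(to_beat_interval(trace(c(600, -1), 1, valid = c(TRUE, TRUE))),
               "non-positive")
})

test_that("window segmentation counts and shapes follow the 2-min/1-min scheme", {
  expect_length(segment_windows(trace(rep(0.1, 600 * 20), 20)), 9)  # 10 min
  expect_length(segment_windows(trace(rep(0.1, 120 * 20), 20)), 1)  # 2 min
  segs <- segment_windows(trace(rep(0.1, 240 * 20), 20))
  expect_true(all(vapply(segs, function(s) all(abs(s) < 1e-12), TRUE)))
  expect_error(segment_windows(trace(rep(0.1, 100 * 20), 20)),
               "shorter than one window")
})

test_that("the periodogram concentrates a pure tone and conserves power", {
  iv <- sine_trace(1.0, 20, 120, amp = 1, offset = 0.1)
  seg <- segment_windows(iv)[[1]]
  psd <- psd_binned(seg)
  in_bin <- psd$power[abs(psd$center - 1.0) < 1e-9]
  expect_gt(in_bin / sum(psd$power), 0.9)
  # binned power == raw periodogram power (conservation by construction)
  expect_lt(abs(sum(psd$power) - attr(psd, "raw_total")) /
              attr(psd, "raw_total"), 1e-9)
  # zero segment -> all-zero PSD
  z <- rep(0, 2400); attr(z, "rate") <- 20
  expect_true(all(psd_binned(z)$power == 0))
})

test_that("windowed tone power matches the analytic amplitude", {
  # a sinusoid of amplitude a carries variance a^2/2
  iv <- sine_trace(2.0, 20, 120, amp = 0.004, offset = 0.1)
  psd <- psd_binned(segment_windows(iv)[[1]])
  expect_equal(sum(psd$power), 0.004^2 / 2, tolerance = 0.02)
})

test_that("band powers split equal tones evenly and flag an empty HF band", {
  mkpsd <- function(f, amp = 1) {
    iv <- sine_trace(f, 20, 120, amp = amp, offset = 0.1)
    psd_binned(segment_windows(iv)[[1]])
  }
  t <- (0:(120 * 20 - 1)) / 20
  two <- trace(0.1 + 0.002 * sin(2 * pi * 1 * t) +
                 0.002 * sin(2 * pi * 2 * t), 20)
  bp <- band_powers(lapply(segment_windows(two), psd_binned))
  expect_equal(bp$lf_hf_ratio, 1.0, tolerance = 0.05)

  lf_only <- band_powers(list(mkpsd(1.0)))
  expect_gt(lf_only$lf / max(lf_only$hf, 1e-300), 1e3)

  flat <- band_powers(list(psd_binned(structure(rep(0, 2400), rate = 20))))
  expect_true(flat$hf_zero)
  expect_true(is.na(flat$lf_hf_ratio))
})

test_that("white-noise intervals give an LF/HF ratio near the bandwidth ratio", {
  set.seed(81)
  iv <- trace(stats::rnorm(20 * 600, 0.1, 0.004), 20)
  bp <- band_powers(lapply(segment_windows(iv), psd_binned))
  # LF spans 12 bins, HF 25 bins on the 0.1 Hz grid
  expect_lt(abs(bp$lf_hf_ratio - 12 / 25), 0.1)
})

test_that("band assignment sweeps correctly across the LF/HF boundary", {
  for (f in c(0.4, 0.8, 1.5)) {
    bp <- band_powers(list(psd_binned(segment_windows(
      sine_trace(f, 20, 120, amp = 0.003, offset = 0.1))[[1]])))
    expect_gt(bp$lf, bp$hf)
  }
  for (f in c(1.6, 2.5, 4.0)) {
    bp <- band_powers(list(psd_binned(segment_windows(
      sine_trace(f, 20, 120, amp = 0.003, offset = 0.1))[[1]])))
    expect_gt(bp$hf, bp$lf)
  }
})

test_that("band powers are invariant to a constant interval offset", {
  base <- sine_trace(1.0, 20, 240, amp = 0.003, offset = 0.1)
  shifted <- trace(base$values + 0.05, 20)
  b1 <- band_powers(lapply(segment_windows(base), psd_binned))
  b2 <- band_powers(lapply(segment_windows(shifted), psd_binned))
  expect_equal(b1$lf, b2$lf, tolerance = 1e-9)
  expect_equal(b1$hf, b2$hf, tolerance = 1e-9)
})

test_that("the full pipeline ratio rises with the LF/HF modulation ratio", {
  ratios <- vapply(c(0.01, 0.02, 0.04), function(d1) {
    p <- quiet_preset(hr_mean = 600,
                      hr_modulations = list(c(1.0, d1), c(2.0, 0.02)),
                      noise_sd = list(hr = 0.5))
    hrv_spectral(gen_hr_series(p, duration_s = 360, rate = 100,
                               seed = 21))$lf_hf_ratio
  }, 0)
  expect_true(all(diff(ratios) > 0))
})
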