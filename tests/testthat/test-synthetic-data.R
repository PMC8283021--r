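test_that("degenerate preset yields a flat waveform with known MAP", {
  p <- quiet_preset(map_light = 100, map_dark = 100, pulse_pressure = 0,
                    bp_circadian_amplitude = 0, bp_animal_sd = 0,
                    noise_sd = list(pressure = 0))
  rec <- gen_bp_telemetry(p, 1, duration_h = 1, rate = 100)[[1]]
  expect_true(all(abs(rec$traces$pressure$values - 100) < 1e-9))
  expect_equal(rec$annotations$hourly_bp$map, 100)
})

test_that("telemetry generation is deterministic and rejects bad durations", {
  p <- quiet_preset()
  a <- gen_bp_telemetry(p, 2, duration_h = 1, rate = 60, seed = 4)
  b <- gen_bp_telemetry(p, 2, duration_h = 1, rate = 60, seed = 4)
  expect_identical(a[[1]]$traces$pressure$values,
                   b[[1]]$traces$pressure$values)
  expect_identical(a[[2]]$annotations$map_offset,
                   b[[2]]$annotations$map_offset)
  expect_error(gen_bp_telemetry(p, 1, duration_h = 0.5), "at least 1 h")
})

test_that("ground-truth phase means equal preset targets up to the animal offset", {
  p <- quiet_preset(bp_animal_sd = 0, noise_sd = list(pressure = 0))
  rec <- gen_bp_telemetry(p, 1, duration_h = 24, rate = 50)[[1]]
  hb <- rec$annotations$hourly_bp
  expect_equal(mean(hb$map[hb$phase == "light"]), p$map_light,
               tolerance = 1e-9)
  expect_equal(mean(hb$map[hb$phase == "dark"]), p$map_dark,
               tolerance = 1e-9)
})

test_that("heart-rate series carries its modulation and injected artifacts", {
  p <- quiet_preset(hr_mean = 600, hr_modulations = list(),
                    noise_sd = list(hr = 0))
  hr <- gen_hr_series(p, duration_s = 10, rate = 50)
  expect_true(all(abs(hr$values - 600) < 1e-9))

  hr_a <- gen_hr_series(p, duration_s = 30, rate = 50,
                        artifacts = list(c(10, 150)))
  expect_equal(sum(hr_a$values < 200), 1L)
  expect_equal(hr_a$values[10 * 50 + 1], 150)
  expect_equal(attr(hr_a, "artifacts")$value_bpm, 150)
  clean <- gen_hr_series(p, duration_s = 30, rate = 50)
  expect_equal(sum(hr_a$values != clean$values), 1L)

  expect_error(synth_preset("bad", hr_modulations = list(c(1, 1.2))),
               "depth")
})

test_that("a single interval modulation concentrates off-DC spectral power at its frequency", {
  # oracle: direct FFT of the constructed beat-interval series
  p <- quiet_preset(hr_mean = 600, hr_modulations = list(c(1.0, 0.05)),
                    noise_sd = list(hr = 0))
  hr <- gen_hr_series(p, duration_s = 120, rate = 20)
  iv <- to_beat_interval(hr)
  x <- iv$values - mean(iv$values)
  P <- Mod(stats::fft(x))^2
  n <- length(x)
  freq <- (seq_len(n) - 1) * 20 / n
  half <- 2:(n %/% 2)
  near <- abs(freq[half] - 1.0) <= 0.1
  expect_gt(sum(P[half][near]) / sum(P[half]), 0.9)
})

test_that("sleep sessions honour zero event rates and Poisson insertion", {
  p0 <- quiet_preset(apnea_rate = 0, desat_rate = 0)
  rec <- gen_sleep_session(p0, duration_h = 0.5, rate_flow = 200,
                           rate_eeg = 100, rate_emg = 100, rate_spo2 = 5)
  expect_equal(nrow(rec$annotations$events), 0L)

  # expected count = rate * hours of sleep
  p <- quiet_preset(apnea_rate = 60)
  counts <- vapply(1:3, function(s) {
    r <- gen_sleep_session(p, duration_h = 1, rate_flow = 200,
                           rate_eeg = 100, rate_emg = 100, rate_spo2 = 5,
                           seed = s)
    ev <- r$annotations$events
    tst_h <- sum(unclass(r$annotations$hypnogram) != "WAKE") * 10 / 3600
    sum(ev$type == "APNEA") / tst_h
  }, 0)
  expect_lt(abs(mean(counts) - 60), 25)  # 3 draws of Poisson(~30)/0.5
})

test_that("generated NREM breaths integrate to the preset tidal volume", {
  p <- quiet_preset(noise_sd = list(flow = 0))
  rec <- gen_sleep_session(p, duration_h = 0.25, rate_flow = 400,
                           rate_eeg = 100, rate_emg = 100, rate_spo2 = 5,
                           seed = 3)
  tb <- rec$annotations$breaths
  nrem <- tb[tb$stage == "NREM" & !tb$ifl, ]
  flow <- rec$traces$flow$values
  # numerically integrate a few inspirations against the annotated volumes
  take <- head(order(nrem$onset), 25)
  for (b in take) {
    i0 <- round(nrem$onset[b] * 400) + 1
    i1 <- i0 + round(nrem$Ti[b] * 400) - 1
    vt_num <- sum(flow[i0:i1]) / 400
    expect_equal(vt_num, nrem$vt[b], tolerance = 0.05)
  }
  expect_equal(mean(tb$vt[tb$stage == "NREM"]), 0.3, tolerance = 0.05)
})

test_that("inserted apnea segments stay at or below 10% of surrounding amplitude", {
  p <- quiet_preset(apnea_rate = 40)
  rec <- gen_sleep_session(p, duration_h = 1, rate_flow = 200,
                           rate_eeg = 100, rate_emg = 100, rate_spo2 = 5,
                           seed = 5)
  flow <- rec$traces$flow
  t <- trace_time(flow)
  ev <- rec$annotations$events
  ev <- ev[ev$type == "APNEA", ]
  expect_gt(nrow(ev), 0)
  for (k in seq_len(nrow(ev))) {
    inside <- t >= ev$start_s[k] + 0.05 &
      t <= ev$start_s[k] + ev$duration_s[k] - 0.05
    before <- t >= ev$start_s[k] - 5 & t < ev$start_s[k] - 0.2
    expect_lte(max(abs(flow$values[inside])),
               0.10 * max(abs(flow$values[before])))
  }
})

test_that("hypoxic challenge ground truth follows the preset levels", {
  p <- quiet_preset()
  rec <- gen_hvr_session(p, body_weight_g = 42, rate_flow = 200,
                         rate_spo2 = 5, seed = 2)
  expect_equal(rec$annotations$hvr, (2.9 - 1.2) / (97 - 63))
  expect_equal(rec$annotations$slope_raw, -rec$annotations$hvr * 42)

  p_flat <- quiet_preset(hvr_params = list(ve_normoxia = 1.2,
                                           ve_hypoxia = 1.2,
                                           spo2_normoxia = 97,
                                           spo2_hypoxia = 63))
  rec2 <- gen_hvr_session(p_flat, rate_flow = 200, rate_spo2 = 5)
  expect_equal(rec2$annotations$hvr, 0)

  a <- gen_hvr_session(p, rate_flow = 100, rate_spo2 = 5, seed = 9)
  b <- gen_hvr_session(p, rate_flow = 100, rate_spo2 = 5, seed = 9)
  expect_identical(a$traces$flow$values, b$traces$flow$values)

  expect_error(synth_preset("bad", hvr_params = list(
    ve_normoxia = 1, ve_hypoxia = 2, spo2_normoxia = 110,
    spo2_hypoxia = 60)), "\\(0, 100\\]")
})
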