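stage_fixture <- function(kind, rate = 100, epoch_s = 10) {
  t <- (0:(epoch_s * rate - 1)) / rate
  switch(kind,
         nrem = list(eeg = 300 * sin(2 * pi * 3 * t), emg = rep(0.01, length(t))),
         rem = list(eeg = 80 * sin(2 * pi * 7 * t), emg = rep(0, length(t))),
         wake = list(eeg = 80 * sin(2 * pi * 7 * t), emg = stats::rnorm(length(t), 0, 2)))
}

test_that("the staging rule classifies canonical epochs", {
  th <- list(theta_m = 1, theta_atonia = 0.3)
  for (kind in c("nrem", "rem", "wake")) {
    fx <- stage_fixture(kind)
    hyp <- score_epochs(trace(fx$eeg, 100, "eeg"), trace(fx$emg, 100, "emg"),
                        thresholds = th)
    expect_equal(as.character(hyp), toupper(kind), label = kind)
  }
  # high EMG forces WAKE regardless of EEG content
  fx <- stage_fixture("nrem")
  hyp <- score_epochs(trace(fx$eeg, 100, "eeg"),
                      trace(rep(5, length(fx$emg)), 100, "emg"),
                      thresholds = th)
  expect_equal(as.character(hyp), "WAKE")
})

test_that("channels covering different durations are rejected", {
  expect_error(score_epochs(trace(rep(1, 2000), 100),
                            trace(rep(1, 1000), 100)),
               "different numbers of epochs")
})

test_that("sleep architecture arithmetic matches its definitions", {
  st <- c(rep("NREM", 1080), rep("REM", 120), rep("WAKE", 960))
  arch <- architecture(hypnogram(st))
  expect_equal(arch$tst_min, 200)
  expect_equal(arch$pct_nrem, 90)
  expect_equal(arch$pct_rem, 10)
  expect_equal(arch$efficiency_pct, 100 * 200 / 360, tolerance = 1e-9)

  all_wake <- architecture(hypnogram(rep("WAKE", 60)))
  expect_true(all_wake$no_sleep)
  expect_true(is.na(all_wake$pct_nrem))
  expect_equal(all_wake$tst_min, 0)

  all_nrem <- architecture(hypnogram(rep("NREM", 60)))
  expect_equal(all_nrem$efficiency_pct, 100)
  expect_equal(all_nrem$pct_nrem, 100)
})

test_that("analysis windows follow the REM-all / NREM-subsample design", {
  # 6 h with NREM available in every 30-min block: at most 12 NREM windows
  st <- rep(c(rep("WAKE", 60), rep("NREM", 100), rep("REM", 20)), 12)
  hyp <- hypnogram(st)
  w <- select_analysis_windows(hyp)
  expect_equal(sum(w$type == "NREM"), 12L)
  expect_true(all(w$duration_s[w$type == "NREM"] == 20))
  # all REM epochs are covered by REM windows
  expect_equal(sum(w$duration_s[w$type == "REM"]), sum(st == "REM") * 10)

  # a block without NREM contributes no window
  st2 <- c(rep("WAKE", 180), rep("NREM", 180))
  w2 <- select_analysis_windows(hypnogram(st2))
  expect_equal(nrow(w2[w2$type == "NREM", ]), 1L)
  expect_equal(w2$start_s[w2$type == "NREM"], 1800)

  # 22 min of REM yields 22 min of REM windows
  st3 <- c(rep("NREM", 100), rep("REM", 132), rep("WAKE", 100))
  w3 <- select_analysis_windows(hypnogram(st3))
  expect_equal(sum(w3$duration_s[w3$type == "REM"]) / 60, 22)
})

test_that("apnea scoring applies the 0.7-s / two-cycle disjunction", {
  hyp_all_nrem <- hypnogram(rep("NREM", 100))
  # 95% reduction lasting 0.7 s (one small 0.7-s cycle; local cycle 0.6 s)
  tr <- recipe_flow(apnea_recipe(k = 1, ttot_small = 0.7), rate = 500)
  ev <- detect_apneas(tr, hyp_all_nrem)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 0.7, tolerance = 0.05)
  expect_equal(ev$stage, "NREM")

  # identical event lasting 0.65 s: under both criteria too short
  tr2 <- recipe_flow(apnea_recipe(k = 1, ttot_small = 0.65), rate = 500)
  expect_equal(nrow(detect_apneas(tr2, hyp_all_nrem)), 0L)

  # 1.3 s of reduction scores via the two-cycle criterion alone
  tr3 <- recipe_flow(apnea_recipe(k = 2, ttot_small = 0.65), rate = 500)
  cfg_no_abs <- cr_config(apnea_min_dur_s = Inf)
  ev3 <- detect_apneas(tr3, hyp_all_nrem, cfg_no_abs)
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$duration_s, 1.3, tolerance = 0.05)
})

test_that("apneas in WAKE are discarded and no-sleep input warns", {
  tr <- recipe_flow(apnea_recipe(k = 2, ttot_small = 0.7), rate = 500)
  all_wake <- hypnogram(rep("WAKE", 100))
  expect_warning(ev <- detect_apneas(tr, all_wake), "no sleep")
  expect_equal(nrow(ev), 0L)
})

test_that("raising the amplitude threshold never lowers the apnea count", {
  p <- quiet_preset(apnea_rate = 40)
  rec <- gen_sleep_session(p, duration_h = 1, rate_flow = 200,
                           rate_eeg = 100, rate_emg = 100, rate_spo2 = 5,
                           seed = 13)
  hyp <- rec$annotations$hypnogram
  br <- segment_breaths(rec$traces$flow)
  n10 <- nrow(detect_apneas(rec$traces$flow, hyp, cr_config(), breaths = br))
  n20 <- nrow(detect_apneas(rec$traces$flow, hyp,
                            cr_config(apnea_amp_frac = 0.20), breaths = br))
  expect_gte(n20, n10)
})

test_that("the apnea index divides events by total sleep time", {
  st <- c(rep("NREM", 1131), rep("REM", 40))  # TST 195.1 min + 0.07 wake
  arch <- architecture(hypnogram(c(st, rep("WAKE", 500))))
  ev <- structure(data.frame(type = rep("APNEA", 102), start_s = 1:102,
                             duration_s = 1, stage = "NREM"),
                  class = c("cr_events", "data.frame"))
  expect_equal(apnea_index(ev, arch), 102 / (arch$tst_min / 60))
  expect_equal(apnea_index(ev, arch), 31.4, tolerance = 0.05)
  expect_equal(apnea_index(ev[0, ], arch), 0)
  arch0 <- architecture(hypnogram(rep("WAKE", 10)))
  expect_true(is.na(apnea_index(ev, arch0)))
  # doubling TST halves the index
  arch2 <- arch; arch2$tst_min <- 2 * arch$tst_min
  expect_equal(apnea_index(ev, arch2), apnea_index(ev, arch) / 2)
})

desat_trace <- function(depth, dur = 30, at = 150, total = 400, rate = 5,
                        base = 97) {
  t <- (0:(total * rate - 1)) / rate
  rel <- (t - at) / dur
  dip <- ifelse(rel >= 0 & rel < 0.3, rel / 0.3,
                ifelse(rel >= 0.3 & rel < 0.7, 1,
                       ifelse(rel >= 0.7 & rel <= 1, (1 - rel) / 0.3, 0)))
  trace(base - depth * dip, rate, "spo2", "%")
}

test_that("desaturation scoring applies the 5-point threshold", {
  hyp <- hypnogram(rep("NREM", 40))
  d6 <- desaturation_events(desat_trace(6), hyp)
  expect_equal(nrow(d6$events), 1L)
  expect_equal(d6$events$stage, "NREM")
  d45 <- desaturation_events(desat_trace(4.5), hyp)
  expect_equal(nrow(d45$events), 0L)

  const <- desaturation_events(trace(rep(97, 2000), 5, "spo2"), hyp)
  expect_equal(nrow(const$events), 0L)
  expect_equal(const$odi, 0)
  expect_equal(unname(const$mean_spo2["NREM"]), 97)

  expect_error(desaturation_events(trace(rep(101, 100), 5), hyp),
               "\\(0, 100\\]")
})

test_that("desaturations with WAKE onset are not counted in the ODI", {
  st <- c(rep("WAKE", 20), rep("NREM", 20))
  d <- desaturation_events(desat_trace(6, at = 100), hypnogram(st))
  expect_equal(nrow(d$events), 0L)
})

test_that("scored hypnogram, apneas and desaturations recover the session truth", {
  p <- preset_nzo_baseline()
  rec <- gen_sleep_session(p, duration_h = 2, rate_flow = 200,
                           rate_eeg = 100, rate_emg = 100, rate_spo2 = 5,
                           seed = 17)
  truth <- rec$annotations
  hyp <- score_epochs(rec$traces$eeg, rec$traces$emg)
  expect_gte(mean(unclass(hyp) == unclass(truth$hypnogram)), 0.9)

  ap <- detect_apneas(rec$traces$flow, hyp)
  ins <- truth$events[truth$events$type == "APNEA", ]
  lam <- nrow(ins)
  expect_gte(nrow(ap), stats::qpois(0.025, lam))
  expect_lte(nrow(ap), stats::qpois(0.975, lam))

  de <- desaturation_events(rec$traces$spo2, hyp)
  ins_d <- truth$events[truth$events$type == "DESAT", ]
  matched <- vapply(ins_d$start_s, function(s)
    any(abs(de$events$start_s - s) < 30), TRUE)
  expect_true(all(matched))
})
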