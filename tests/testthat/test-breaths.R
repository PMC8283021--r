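test_that("a pure sinusoid segments into breaths with the closed-form volume", {
  # period 0.6 s, amplitude 1.571 mL/s: V_T = A*T/pi = 0.300 mL, DC = 0.5
  tr <- sine_trace(1 / 0.6, 1000, 60, amp = 1.571, label = "flow",
                   units = "mL/s")
  br <- segment_breaths(tr)
  expect_equal(nrow(br), 99L, tolerance = 1)  # ~100 cycles, edges dropped
  expect_equal(mean(br$RR), 100, tolerance = 0.5)
  expect_equal(mean(br$V_T), 1.571 * 0.6 / pi, tolerance = 0.005)
  expect_equal(mean(br$DC), 0.5, tolerance = 0.02)
})

test_that("all-zero flow yields an empty table and gaps emit no breaths", {
  expect_equal(nrow(segment_breaths(trace(rep(0, 2000), 1000))), 0L)
  rec <- rbind(apnea_recipe(n_pre = 5, k = 0, n_post = 0),
               data.frame(Ttot = 1, amp = 0),       # 1-s silent gap
               apnea_recipe(n_pre = 5, k = 0, n_post = 0))
  tr <- recipe_flow(rec, rate = 500)
  br <- segment_breaths(tr)
  gap_start <- 5 * 0.6
  inside <- br$onset > gap_start + 0.05 & br$onset < gap_start + 0.95
  expect_equal(sum(inside), 0L)
})

test_that("per-breath identities hold on randomized breath trains", {
  set.seed(14)
  for (rep in 1:3) {
    recipe <- data.frame(Ttot = stats::runif(40, 0.4, 0.8),
                         amp = stats::runif(40, 2, 4),
                         dc = stats::runif(40, 0.3, 0.5))
    br <- segment_breaths(recipe_flow(recipe, rate = 1000))
    expect_gt(nrow(br), 30)
    expect_true(all(br$Ti > 0 & br$Ti < br$Ttot))
    expect_true(all(br$DC > 0 & br$DC < 1))
    expect_true(all(abs(br$MIFR - br$V_T / br$Ti) < 1e-6 * br$MIFR))
    expect_true(all(abs(br$VE_inst - br$V_T * 60 / br$Ttot) < 1e-9))
  }
})

test_that("breath count is amplitude-invariant and V_T scales linearly", {
  recipe <- apnea_recipe(n_pre = 30, k = 0, n_post = 0)
  b1 <- segment_breaths(recipe_flow(recipe, rate = 500))
  recipe2 <- recipe; recipe2$amp <- recipe2$amp * 3
  b2 <- segment_breaths(recipe_flow(recipe2, rate = 500))
  expect_equal(nrow(b1), nrow(b2))
  expect_equal(mean(b2$V_T) / mean(b1$V_T), 3, tolerance = 0.01)
})

test_that("summed breath volumes reproduce minute ventilation for steady breathing", {
  recipe <- apnea_recipe(n_pre = 50, k = 0, n_post = 0)
  tr <- recipe_flow(recipe, rate = 500)
  br <- segment_breaths(tr)
  window_s <- diff(range(br$onset)) + mean(br$Ttot)
  ve_sum <- sum(br$V_T) / window_s * 60
  ve <- minute_ventilation(br, 1)$ve_ml_min
  expect_lt(abs(ve_sum - ve) / ve, 0.01)
})

test_that("minute ventilation normalizes by body weight", {
  br <- segment_breaths(recipe_flow(
    data.frame(Ttot = rep(0.5, 20), amp = 0.42 * pi / (2 * 0.5 * 0.4)),
    rate = 500))
  # V_T 0.42 mL at RR 120 -> V_E 50.4 mL/min; at 42 g -> 1.2 mL/min/g
  mv <- minute_ventilation(br, 42)
  expect_equal(mv$ve_ml_min, 50.4, tolerance = 0.5)
  expect_equal(mv$ve_norm, 1.2, tolerance = 0.015)
  mv2 <- minute_ventilation(br, 84)
  expect_equal(mv2$ve_norm, mv$ve_norm / 2)
  one <- br[1, ]
  expect_equal(minute_ventilation(one, 42)$ve_ml_min,
               one$V_T * 60 / one$Ttot)
  expect_error(minute_ventilation(br[0, ], 42), "empty")
})

test_that("breath metrics on sleep-session truth are recovered within tolerance", {
  p <- quiet_preset(apnea_rate = 0, desat_rate = 0)
  rec <- gen_sleep_session(p, duration_h = 0.25, rate_flow = 400,
                           rate_eeg = 100, rate_emg = 100, rate_spo2 = 5,
                           seed = 6)
  br <- segment_breaths(rec$traces$flow)
  tb <- rec$annotations$breaths
  # match detected to truth breaths by onset
  idx <- findInterval(br$onset + 0.02, tb$onset)
  ok <- idx >= 1 & abs(tb$onset[idx] - br$onset) < 0.1
  expect_gt(mean(ok), 0.95)
  rel_vt <- abs(br$V_T[ok] - tb$vt[idx[ok]]) / tb$vt[idx[ok]]
  rel_rr <- abs(60 / br$Ttot[ok] - 60 / tb$Ttot[idx[ok]]) /
    (60 / tb$Ttot[idx[ok]])
  expect_lt(stats::median(rel_vt), 0.05)
  expect_lt(stats::median(rel_rr), 0.02)
})

ifl_fixture <- function(clip = NULL, ramp = 0, n = 10, rate = 1000) {
  ti <- 0.2; te <- 0.36
  flow <- numeric(0); eff <- numeric(0)
  for (i in seq_len(n)) {
    ph <- seq(0, 1, length.out = ti * rate)
    fi <- 3 * sin(pi * ph)
    if (!is.null(clip))
      fi <- pmin(fi, ifelse(ph >= 0.2 & ph <= 0.8, clip * 3, 3))
    pe <- seq(0, 1, length.out = te * rate)
    flow <- c(flow, fi, -3 * ti / te * sin(pi * pe))
    eff <- c(eff, sin(pi * ph) * (1 + ramp * ph), rep(0, length(pe)))
  }
  list(flow = trace(flow, rate, "flow", "mL/s"),
       effort = trace(eff, rate, "effort"))
}

test_that("IFL flags demand an early plateau with rising effort", {
  plain <- ifl_fixture()
  br <- detect_ifl(segment_breaths(plain$flow), plain$flow, plain$effort)
  expect_true(all(!br$ifl))

  clipped <- ifl_fixture(clip = 0.6, ramp = 0.8)
  br2 <- detect_ifl(segment_breaths(clipped$flow), clipped$flow,
                    clipped$effort)
  expect_true(all(br2$ifl))

  flat_effort <- ifl_fixture(clip = 0.6, ramp = 0)
  br3 <- detect_ifl(segment_breaths(flat_effort$flow), flat_effort$flow,
                    flat_effort$effort)
  expect_true(all(!br3$ifl))

  expect_warning(br4 <- detect_ifl(segment_breaths(plain$flow), plain$flow,
                                   NULL), "effort")
  expect_true(all(is.na(br4$ifl)))
})
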