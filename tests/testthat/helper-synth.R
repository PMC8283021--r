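# Shared fixtures, built in code.

# A sinusoidal trace.
sine_trace <- function(freq, rate, dur_s, amp = 1, offset = 0,
                       label = "signal", units = "") {
  t <- (seq_len(round(dur_s * rate)) - 1) / rate
  trace(offset + amp * sin(2 * pi * freq * t), rate, label, units)
}

# Airflow built from an explicit breath recipe: data.frame with columns
# Ttot (s), amp (peak inspiratory flow, mL/s) and optionally dc. Each breath
# is a half-sine inspiration over dc*Ttot and a volume-balancing half-sine
# expiration. Used to construct exact apnea/scoring scenarios.
recipe_flow <- function(recipe, rate = 1000, dc = 0.4, lead_s = 0) {
  if (is.null(recipe$dc)) recipe$dc <- dc
  flow <- rep(0, round(lead_s * rate))
  for (b in seq_len(nrow(recipe))) {
    ti <- recipe$dc[b] * recipe$Ttot[b]
    te <- recipe$Ttot[b] - ti
    ni <- round(ti * rate); ne <- round(te * rate)
    insp <- recipe$amp[b] * sin(pi * seq(0, 1, length.out = ni))
    ex <- -recipe$amp[b] * (ti / te) * sin(pi * seq(0, 1, length.out = ne))
    flow <- c(flow, insp, ex)
  }
  trace(c(flow, rep(0, rate)), rate, "flow", "mL/s")
}

# n normal breaths, then k reduced breaths (amplitude frac), then n normal.
apnea_recipe <- function(n_pre = 20, k = 2, n_post = 10, ttot_normal = 0.6,
                         ttot_small = ttot_normal, amp = 3, frac = 0.05) {
  data.frame(
    Ttot = c(rep(ttot_normal, n_pre), rep(ttot_small, k),
             rep(ttot_normal, n_post)),
    amp = c(rep(amp, n_pre), rep(amp * frac, k), rep(amp, n_post)))
}

# Hypnogram long enough to cover a trace, all one stage.
hyp_covering <- function(tr, stage = "NREM") {
  hypnogram(rep(stage, ceiling(trace_duration(tr) / 10)))
}

# Hand-built beat series (times in s) with constant SBP/DBP.
const_beats <- function(dur_h, sbp = 135, dbp = 95, per_s = 10,
                        start_clock = 9) {
  times <- seq(0, dur_h * 3600 - 1 / per_s, by = 1 / per_s)
  structure(data.frame(beat_times = times, sbp = sbp, dbp = dbp),
            class = c("cr_beats", "data.frame"),
            duration_s = dur_h * 3600, start_clock = start_clock)
}

# Fast, small presets for generator tests.
quiet_preset <- function(...) synth_preset("test", seed = 99L, ...)
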