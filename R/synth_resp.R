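# Synthetic plethysmography sessions: stage-dependent breathing with
# programmable apneas and flow-limited breaths, EEG/EMG driven by a
# generated hypnogram, SpO2 with desaturation events, and the
# normoxia-to-hypoxia challenge.

# Draw a hypnogram as alternating WAKE -> NREM (-> REM) bouts whose mean
# lengths and branching probability are chosen so the expected stage
# fractions match the preset targets. REM bouts last at least 2 epochs.
gen_hypnogram_stages <- function(preset, n_epochs, epoch_s = 10) {
  f_w <- 1 - preset$sleep_frac
  f_n <- preset$sleep_frac * preset$nrem_frac_of_sleep
  f_r <- preset$sleep_frac * (1 - preset$nrem_frac_of_sleep)
  m_n <- max(1, preset$mean_bout_s[["NREM"]] / epoch_s)
  m_r <- max(2, preset$mean_bout_s[["REM"]] / epoch_s)
  m_w <- m_n * f_w / f_n
  p_rem <- min(1, (f_r / f_n) * (m_n / m_r))

  draw_bout <- function(mean_ep, min_ep = 1) {
    mu <- max(mean_ep - min_ep, 1e-6)
    min_ep + stats::rgeom(1, 1 / (1 + mu))
  }
  stages <- character(0)
  while (length(stages) < n_epochs) {
    stages <- c(stages, rep("WAKE", draw_bout(m_w)),
                rep("NREM", draw_bout(m_n)))
    if (stats::runif(1) < p_rem)
      stages <- c(stages, rep("REM", draw_bout(m_r, min_ep = 2)))
  }
  stages[seq_len(n_epochs)]
}

# Build a per-breath table over piecewise-constant parameter segments.
# Each breath: half-sine inspiration over Ti = dc * Ttot, half-sine
# expiration over the remainder, amplitudes chosen so inspired and expired
# volumes balance. Breaths never straddle a segment boundary; a residual
# sub-cycle gap may remain at each boundary.
build_breath_train <- function(segments, ttot_jitter = 0.03,
                               vt_jitter = 0.05) {
  out <- vector("list", nrow(segments))
  for (s in seq_len(nrow(segments))) {
    seg <- segments[s, ]
    len <- seg$end_s - seg$start_s
    mean_ttot <- 60 / seg$rr
    n_est <- ceiling(len / mean_ttot * 1.25) + 3L
    ttot <- mean_ttot * exp(stats::rnorm(n_est, 0, ttot_jitter))
    onset <- seg$start_s + c(0, cumsum(ttot[-n_est]))
    keep <- onset + ttot <= seg$end_s + 1e-9
    if (!any(keep)) next
    ttot <- ttot[keep]; onset <- onset[keep]
    nb <- length(ttot)
    vt <- seg$vt * exp(stats::rnorm(nb, 0, vt_jitter))
    ti <- seg$dc * ttot
    ifl <- stats::runif(nb) < seg$ifl_frac
    out[[s]] <- data.frame(
      onset = onset, Ttot = ttot, Ti = ti, Te = ttot - ti, vt = vt,
      stage = seg$stage, ifl = ifl, scale = 1, segment = s)
  }
  br <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  br$amp_i <- pi * br$vt / (2 * br$Ti)
  br$amp_e <- pi * br$vt / (2 * br$Te)
  rownames(br) <- NULL
  br
}

# Render a breath table into airflow and respiratory-effort sample vectors.
# IFL breaths are amplitude-clipped at `ifl_clip` of the unclipped peak over
# 20-80% of Ti and carry a rising effort envelope.
sample_breath_train <- function(breaths, duration_s, rate, noise_sd = 0,
                                ifl_clip = 0.6, effort_noise = 0.02) {
  n <- as.integer(round(duration_s * rate))
  t <- (seq_len(n) - 1L) / rate
  k <- findInterval(t, breaths$onset)
  flow <- numeric(n)
  effort <- numeric(n)
  inb <- k >= 1L
  ki <- k[inb]
  tau <- t[inb] - breaths$onset[ki]
  phase_i <- tau / breaths$Ti[ki]
  in_insp <- phase_i < 1
  in_exp <- !in_insp & tau < breaths$Ttot[ki]

  f <- numeric(sum(inb))
  f[in_insp] <- (breaths$amp_i[ki] * sin(pi * phase_i))[in_insp]
  clipm <- in_insp & breaths$ifl[ki] & phase_i >= 0.2 & phase_i <= 0.8
  f[clipm] <- pmin(f[clipm], (ifl_clip * breaths$amp_i[ki])[clipm])
  pe <- ((tau - breaths$Ti[ki]) / breaths$Te[ki])
  f[in_exp] <- (-breaths$amp_e[ki] * sin(pi * pe))[in_exp]
  f <- f * breaths$scale[ki]
  flow[inb] <- f

  e <- numeric(sum(inb))
  ramp <- 1 + 0.8 * phase_i * breaths$ifl[ki]
  e[in_insp] <- (sin(pi * phase_i) * ramp)[in_insp]
  effort[inb] <- e

  if (noise_sd > 0) flow <- flow + stats::rnorm(n, 0, noise_sd)
  if (effort_noise > 0) effort <- effort + stats::rnorm(n, 0, effort_noise)
  list(flow = flow, effort = effort)
}

#' Generate a synthetic polysomnography session
#'
#' Produces a full light-phase sleep study driven by a generated hypnogram:
#' EEG with high-amplitude 2-5 Hz activity in NREM and low-amplitude
#' 5-10 Hz activity in REM, EMG with stage-dependent tonus and REM atonia,
#' calibrated airflow with stage-specific breathing (apneas inserted as a
#' Poisson process over sleep at the preset rate, each silencing 3-5 whole
#' breath cycles to 5% amplitude, i.e. a >= 90% reduction lasting >= 0.7 s;
#' flow-limited breaths at the preset per-stage fraction), a respiratory
#' effort channel, and SpO2 with piecewise-linear desaturation dips of the
#' preset depth. The true hypnogram, event list and per-breath table are
#' attached as annotations.
#'
#' @param preset a [synth_preset()].
#' @param duration_h session length in hours (default 6, 10 AM to 4 PM).
#' @param rate_flow,rate_eeg,rate_emg,rate_spo2 channel sampling rates in Hz
#'   (defaults 1000/1000/1000/100, configurable downward for speed).
#' @param seed integer seed.
#' @param start_clock clock hour of session start (default 10).
#' @param group group label.
#' @return a [recording()] with traces `flow` (mL/s), `effort` (a.u.),
#'   `eeg` (uV), `emg` (mV), `spo2` (%).
#' @export
gen_sleep_session <- function(preset, duration_h = 6, rate_flow = 1000,
                              rate_eeg = 1000, rate_emg = rate_eeg,
                              rate_spo2 = 100, seed = preset$seed,
                              start_clock = 10, group = "control") {
  if (preset$apnea_rate < 0) stop("apnea_rate must be non-negative")
  epoch_s <- 10
  n_epochs <- as.integer(round(duration_h * 3600 / epoch_s))
  duration_s <- n_epochs * epoch_s

  with_seed(seed, {
    stages <- gen_hypnogram_stages(preset, n_epochs, epoch_s)
    hyp <- hypnogram(stages, epoch_s = epoch_s, start_clock = start_clock)

    runs <- rle(stages)
    ends <- cumsum(runs$lengths) * epoch_s
    segments <- data.frame(
      start_s = c(0, ends[-length(ends)]), end_s = ends, stage = runs$values)
    bp <- preset$breath_params
    segments$vt <- vapply(segments$stage, function(s) bp[[s]]$vt, 0)
    segments$rr <- vapply(segments$stage, function(s) bp[[s]]$rr, 0)
    segments$dc <- vapply(segments$stage, function(s) bp[[s]]$dc, 0)
    segments$ifl_frac <- vapply(segments$stage, function(s) bp[[s]]$ifl_frac, 0)
    breaths <- build_breath_train(segments)

    # --- apnea insertion: silence whole breath cycles during sleep -------
    tst_h <- sum(stages != "WAKE") * epoch_s / 3600
    n_apnea <- stats::rpois(1, preset$apnea_rate * tst_h)
    cyc_rng <- preset$apnea_cycles_range
    seg_of <- breaths$segment
    sleep_breath <- breaths$stage != "WAKE"
    events <- list()
    chosen <- integer(0)
    if (n_apnea > 0) {
      for (ev in seq_len(n_apnea)) {
        k_cyc <- sample(seq(cyc_rng[1], cyc_rng[2]), 1)
        ok <- FALSE
        for (try in seq_len(200)) {
          i <- sample(which(sleep_breath), 1)
          j <- i + k_cyc - 1L
          if (i <= 15L || j > nrow(breaths)) next
          # stay within one bout, at least two breaths clear of its start so
          # the scored onset cannot spill into the preceding epoch
          if (seg_of[j] != seg_of[i] || seg_of[i - 2L] != seg_of[i]) next
          if (length(chosen) && min(abs(chosen - i)) < 20L) next
          ok <- TRUE
          break
        }
        if (!ok) next
        chosen <- c(chosen, i)
        breaths$scale[i:j] <- 0.05
        events[[length(events) + 1L]] <- data.frame(
          type = "APNEA", start_s = breaths$onset[i],
          duration_s = sum(breaths$Ttot[i:j]), stage = breaths$stage[i])
      }
    }

    fx <- sample_breath_train(breaths, duration_s, rate_flow,
                              noise_sd = preset$noise_sd$flow %||% 0)

    # --- EEG / EMG, epoch-wise stage-dependent ---------------------------
    eeg_amp <- c(WAKE = 80, NREM = 300, REM = 100)
    eeg_frq <- c(WAKE = 8, NREM = 3.5, REM = 7)
    emg_amp <- c(WAKE = 1.0, NREM = 0.3, REM = 0.05)
    phi <- stats::runif(n_epochs, 0, 2 * pi)
    n_eeg <- duration_s * rate_eeg
    te <- (seq_len(n_eeg) - 1L) / rate_eeg
    ep <- pmin(n_epochs, as.integer(te / epoch_s) + 1L)
    st_ep <- stages[ep]
    eeg <- eeg_amp[st_ep] * sin(2 * pi * eeg_frq[st_ep] * te + phi[ep]) +
      stats::rnorm(n_eeg, 0, preset$noise_sd$eeg %||% 0)
    n_emg <- duration_s * rate_emg
    ep_m <- pmin(n_epochs, as.integer(((seq_len(n_emg) - 1L) / rate_emg) /
                                        epoch_s) + 1L)
    emg <- emg_amp[stages[ep_m]] * stats::rnorm(n_emg)

    # --- SpO2 with desaturation dips ------------------------------------
    n_spo2 <- as.integer(duration_s * rate_spo2)
    ts <- (seq_len(n_spo2) - 1L) / rate_spo2
    spo2 <- preset$spo2_baseline +
      stats::rnorm(n_spo2, 0, preset$noise_sd$spo2 %||% 0)
    n_desat <- stats::rpois(1, preset$desat_rate * tst_h)
    sleep_ep <- which(stages != "WAKE")
    desat_starts <- numeric(0)
    if (n_desat > 0 && length(sleep_ep)) {
      for (ev in seq_len(n_desat)) {
        dur <- stats::runif(1, preset$desat_dur_range[1],
                            preset$desat_dur_range[2])
        ok <- FALSE
        for (try in seq_len(200)) {
          t0 <- (sample(sleep_ep, 1) - 1L) * epoch_s +
            stats::runif(1, 0, epoch_s)
          if (t0 + dur > duration_s - 1) next
          # the falling limb must stay within sleep so the event is
          # attributable to sleep by any onset convention
          ep_fall <- (as.integer(t0 / epoch_s) + 1L):
            min(n_epochs, as.integer((t0 + 0.4 * dur) / epoch_s) + 1L)
          if (any(stages[ep_fall] == "WAKE")) next
          if (length(desat_starts) &&
              min(abs(desat_starts - t0)) < dur + 120) next
          ok <- TRUE
          break
        }
        if (!ok) next
        desat_starts <- c(desat_starts, t0)
        rel <- (ts - t0) / dur
        dip <- numeric(n_spo2)
        w <- rel >= 0 & rel < 0.3
        dip[w] <- rel[w] / 0.3
        w <- rel >= 0.3 & rel < 0.7
        dip[w] <- 1
        w <- rel >= 0.7 & rel <= 1
        dip[w] <- (1 - rel[w]) / 0.3
        spo2 <- spo2 - preset$desat_depth * dip
        st0 <- stages[min(n_epochs, as.integer(t0 / epoch_s) + 1L)]
        events[[length(events) + 1L]] <- data.frame(
          type = "DESAT", start_s = t0, duration_s = dur, stage = st0)
      }
    }
    spo2 <- pmin(spo2, 100)

    truth_events <- if (length(events)) {
      ev <- do.call(rbind, events)
      ev[order(ev$type, ev$start_s), , drop = FALSE]
    } else {
      data.frame(type = character(0), start_s = numeric(0),
                 duration_s = numeric(0), stage = character(0))
    }
    rownames(truth_events) <- NULL

    recording(
      animal_id = sprintf("%s-psg", preset$name), group = group,
      body_weight_g = preset$body_weight_g, lights_on_hour = 9,
      traces = list(
        flow = trace(fx$flow, rate_flow, "flow", "mL/s", start_clock),
        effort = trace(fx$effort, rate_flow, "effort", "a.u.", start_clock),
        eeg = trace(eeg, rate_eeg, "eeg", "uV", start_clock),
        emg = trace(emg, rate_emg, "emg", "mV", start_clock),
        spo2 = trace(spo2, rate_spo2, "spo2", "%", start_clock)),
      annotations = list(hypnogram = hyp, events = truth_events,
                         breaths = breaths))
  })
}

#' Generate a synthetic normoxia-to-hypoxia challenge session
#'
#' Emulates the hypoxic ventilatory response protocol: 20 min of quiet
#' normoxic breathing (minute ventilation `ve_normoxia * body_weight`,
#' SpO2 at the normoxic level) followed by 5 min of hypoxia, with
#' ventilation and saturation ramping linearly to their hypoxic plateaus
#' within `transition_s` seconds of the switch. The ground-truth HVR slope
#' `(ve_hypoxia - ve_normoxia) / (spo2_normoxia - spo2_hypoxia)`
#' (mL/min/g per %SpO2) is attached as an annotation.
#'
#' @param preset a [synth_preset()].
#' @param body_weight_g body weight used to scale absolute ventilation
#'   (default from preset).
#' @param onset_s time of the hypoxic switch (default 1200 s).
#' @param duration_s total session length (default 1500 s).
#' @param transition_s ramp duration after the switch (default 30 s).
#' @param rate_flow,rate_spo2 sampling rates in Hz.
#' @param seed integer seed.
#' @param group group label.
#' @return a [recording()] with traces `flow` (mL/s) and `spo2` (%).
#' @export
gen_hvr_session <- function(preset, body_weight_g = preset$body_weight_g,
                            onset_s = 1200, duration_s = 1500,
                            transition_s = 30, rate_flow = 1000,
                            rate_spo2 = 100, seed = preset$seed,
                            group = "control") {
  hp <- preset$hvr_params
  if (hp$spo2_normoxia <= 0 || hp$spo2_normoxia > 100 ||
      hp$spo2_hypoxia <= 0 || hp$spo2_hypoxia > 100)
    stop("SpO2 levels must lie in (0, 100]")
  stopifnot(onset_s > 0, duration_s > onset_s)

  rr_n <- 120; rr_h <- 160; dc <- 0.35
  ve_n <- hp$ve_normoxia * body_weight_g     # mL/min
  ve_h <- hp$ve_hypoxia * body_weight_g

  with_seed(seed, {
    # piecewise-constant parameter segments; the ramp is approximated in
    # 3-s steps so ventilation reaches its hypoxic plateau within the ramp
    step_s <- 3
    ramp_edges <- seq(onset_s, onset_s + transition_s, by = step_s)
    seg_start <- c(0, ramp_edges[-length(ramp_edges)], onset_s + transition_s)
    seg_end <- c(ramp_edges, duration_s)
    lambda <- pmin(1, pmax(0, ((seg_start + seg_end) / 2 - onset_s) /
                             transition_s))
    lambda[1] <- 0
    rr <- (1 - lambda) * rr_n + lambda * rr_h
    ve <- (1 - lambda) * ve_n + lambda * ve_h
    segments <- data.frame(start_s = seg_start, end_s = seg_end,
                           stage = "WAKE", vt = ve / rr, rr = rr, dc = dc,
                           ifl_frac = 0)
    breaths <- build_breath_train(segments, ttot_jitter = 0.02,
                                  vt_jitter = 0.03)
    fx <- sample_breath_train(breaths, duration_s, rate_flow,
                              noise_sd = preset$noise_sd$flow %||% 0)

    n_spo2 <- as.integer(duration_s * rate_spo2)
    ts <- (seq_len(n_spo2) - 1L) / rate_spo2
    lam_s <- pmin(1, pmax(0, (ts - onset_s) / transition_s))
    spo2 <- (1 - lam_s) * hp$spo2_normoxia + lam_s * hp$spo2_hypoxia +
      stats::rnorm(n_spo2, 0, preset$noise_sd$spo2 %||% 0)
    spo2 <- pmin(spo2, 100)

    hvr_truth <- (hp$ve_hypoxia - hp$ve_normoxia) /
      (hp$spo2_normoxia - hp$spo2_hypoxia)
    recording(
      animal_id = sprintf("%s-hvr", preset$name), group = group,
      body_weight_g = body_weight_g, lights_on_hour = 9,
      traces = list(
        flow = trace(fx$flow, rate_flow, "flow", "mL/s"),
        spo2 = trace(spo2, rate_spo2, "spo2", "%")),
      annotations = list(
        hypoxia_onset_s = onset_s,
        hvr = hvr_truth,
        slope_raw = -hvr_truth * body_weight_g,
        ve_normoxia = hp$ve_normoxia, ve_hypoxia = hp$ve_hypoxia,
        spo2_normoxia = hp$spo2_normoxia, spo2_hypoxia = hp$spo2_hypoxia))
  })
}
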