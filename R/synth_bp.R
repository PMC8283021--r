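# Synthetic blood-pressure telemetry and heart-rate channels.

# Mean over one clock-aligned hour of the 12-h-period circadian sine
# A*sin(2*pi*u/12), where u0 is the hour offset within the phase.
circ_hour_mean <- function(A, u0) {
  A * 12 / (2 * pi) * (cos(2 * pi * u0 / 12) - cos(2 * pi * (u0 + 1) / 12))
}

#' Generate a cohort of synthetic arterial-pressure telemetry recordings
#'
#' Emulates chronic femoral telemetry: a pulsatile arterial waveform whose
#' per-beat systolic/diastolic envelope follows the preset's light/dark MAP
#' targets, a smooth 12-h-period circadian modulation with zero mean within
#' each phase (so phase means equal the preset targets exactly), a random
#' per-animal MAP offset, and additive measurement noise. The waveform is a
#' per-beat raised cosine between DBP and SBP at the preset heart rate.
#'
#' A ground-truth hourly SBP/DBP/MAP table and the per-animal phase targets
#' are attached to each recording's annotations.
#'
#' @param preset a [synth_preset()].
#' @param n_animals number of animals to simulate.
#' @param duration_h recording duration in hours (default from preset; >= 1).
#' @param rate waveform sampling rate in Hz (default 400, configurable
#'   downward for speed).
#' @param seed integer seed (default from preset).
#' @param lights_on_hour clock hour of lights-on; the recording starts at
#'   lights-on.
#' @param group group label stored on each recording.
#' @return list of [recording()]s with a `"pressure"` trace (mmHg).
#' @export
gen_bp_telemetry <- function(preset, n_animals, duration_h = preset$duration_h,
                             rate = 400, seed = preset$seed,
                             lights_on_hour = 9, group = "control") {
  if (duration_h < 1) stop("duration must be at least 1 h")
  if (n_animals < 1) stop("n_animals must be >= 1")
  pp <- preset$pulse_pressure
  A <- preset$bp_circadian_amplitude
  nsd <- preset$noise_sd$pressure %||% 0
  n_hours <- as.integer(floor(duration_h))
  samples_h <- as.integer(round(3600 * rate))

  with_seed(seed, {
    lapply(seq_len(n_animals), function(i) {
      offset <- stats::rnorm(1, 0, preset$bp_animal_sd)
      values <- numeric(n_hours * samples_h)
      hourly <- data.frame(hour = seq_len(n_hours) - 1L, clock_hour = NA_real_,
                           phase = NA_character_, sbp = NA_real_,
                           dbp = NA_real_, map = NA_real_)
      for (h in seq_len(n_hours) - 1L) {
        t <- (h * 3600) + (seq_len(samples_h) - 1L) / rate
        u <- (t / 3600) %% 12                       # hours into current phase
        light <- ((t / 3600) %% 24) < 12            # recording starts at lights-on
        map_t <- ifelse(light, preset$map_light, preset$map_dark) + offset +
          A * sin(2 * pi * u / 12)
        dbp_t <- map_t - pp / 3
        beat_phase <- t * preset$hr_mean / 60
        values[h * samples_h + seq_len(samples_h)] <-
          dbp_t + pp * (1 - cos(2 * pi * beat_phase)) / 2 +
          stats::rnorm(samples_h, 0, nsd)

        u0 <- h %% 12
        map_h <- ifelse(h %% 24 < 12, preset$map_light, preset$map_dark) +
          offset + circ_hour_mean(A, u0)
        hourly$clock_hour[h + 1L] <- (lights_on_hour + h) %% 24
        hourly$phase[h + 1L] <- if (h %% 24 < 12) "light" else "dark"
        hourly$map[h + 1L] <- map_h
        hourly$dbp[h + 1L] <- map_h - pp / 3
        hourly$sbp[h + 1L] <- map_h + 2 * pp / 3
      }
      recording(
        animal_id = sprintf("%s-bp%02d", preset$name, i), group = group,
        body_weight_g = preset$body_weight_g,
        lights_on_hour = lights_on_hour,
        traces = list(pressure = trace(values, rate, "pressure", "mmHg",
                                       start_clock = lights_on_hour)),
        annotations = list(
          hourly_bp = hourly,
          phase_map = c(light = preset$map_light + offset,
                        dark = preset$map_dark + offset),
          map_offset = offset))
    })
  })
}

#' Generate a synthetic instantaneous heart-rate channel
#'
#' Produces a uniformly sampled heart-rate trace (bpm) whose beat-to-beat
#' interval carries sinusoidal modulations at the preset frequencies:
#' `interval(t) = (60/hr_mean) * (1 + sum_k depth_k * sin(2*pi*f_k*t))`,
#' `hr(t) = 60 / interval(t)` plus additive noise. Optional artifacts
#' (deliberately out-of-range readings) are injected at stated times and
#' recorded in the ground truth.
#'
#' @param preset a [synth_preset()].
#' @param duration_s duration in seconds.
#' @param rate sampling rate in Hz (default 100).
#' @param artifacts optional data.frame or list of `c(time_s, value_bpm)`
#'   excursions to inject (values may violate the 200-800 bpm range).
#' @param seed integer seed.
#' @return a [trace()] in bpm with attributes `"artifacts"` (data.frame)
#'   and `"modulations"` (the preset's modulation list).
#' @export
gen_hr_series <- function(preset, duration_s = 600, rate = 100,
                          artifacts = NULL, seed = preset$seed) {
  stopifnot(duration_s > 0)
  for (m in preset$hr_modulations)
    if (m[2] >= 1) stop("modulation depth >= 1 yields non-positive intervals")
  n <- as.integer(round(duration_s * rate))
  t <- (seq_len(n) - 1L) / rate
  interval <- rep(60 / preset$hr_mean, n)
  for (m in preset$hr_modulations)
    interval <- interval + (60 / preset$hr_mean) * m[2] * sin(2 * pi * m[1] * t)
  nsd <- preset$noise_sd$hr %||% 0
  hr <- with_seed(seed, 60 / interval + stats::rnorm(n, 0, nsd))

  art <- data.frame(time_s = numeric(0), value_bpm = numeric(0))
  if (!is.null(artifacts)) {
    if (is.data.frame(artifacts)) {
      art <- data.frame(time_s = artifacts[[1]], value_bpm = artifacts[[2]])
    } else {
      art <- do.call(rbind, lapply(artifacts, function(a)
        data.frame(time_s = a[1], value_bpm = a[2])))
    }
    idx <- pmin(pmax(as.integer(round(art$time_s * rate)) + 1L, 1L), n)
    hr[idx] <- art$value_bpm
  }
  tr <- trace(hr, rate, "heart_rate", "bpm")
  attr(tr, "artifacts") <- art
  attr(tr, "modulations") <- preset$hr_modulations
  tr
}
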