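#' Synthetic study preset
#'
#' A preset bundles every parameter the synthetic-signal generators need to
#' emulate one experimental condition of the study design: circadian blood
#' pressure, heart-rate modulation structure, sleep architecture, stage
#' dependent breathing with programmable apneas/flow-limited breaths, SpO2
#' desaturations, and the hypoxic-challenge ventilation/saturation levels.
#' Presets are deterministic: the same preset and seed yield bit-identical
#' signals.
#'
#' Blood pressure is parametrized by the target mean arterial pressure (MAP)
#' per circadian phase plus a pulse pressure; per-beat systolic/diastolic
#' levels follow from the one-third pulse-pressure rule
#' (`DBP = MAP - PP/3`, `SBP = DBP + PP`).
#'
#' @param name preset identifier.
#' @param duration_h telemetry duration in hours.
#' @param map_light,map_dark target light/dark-phase MAP in mmHg.
#' @param pulse_pressure SBP-DBP difference in mmHg.
#' @param bp_circadian_amplitude amplitude (mmHg) of a smooth 12-h-period
#'   modulation superimposed within each phase (zero phase-mean, so phase
#'   targets are preserved exactly).
#' @param bp_animal_sd between-animal SD of the MAP offset, mmHg.
#' @param hr_mean mean heart rate, bpm.
#' @param hr_modulations list of `c(frequency_hz, depth)` sinusoidal
#'   modulations of the beat-to-beat interval; each depth must be < 1.
#' @param sleep_frac,nrem_frac_of_sleep fraction of recording asleep and
#'   NREM fraction of total sleep time.
#' @param mean_bout_s named vector of mean bout lengths (s) for NREM and REM.
#' @param apnea_rate inserted apneas per hour of sleep.
#' @param apnea_cycles_range whole breath cycles silenced per apnea (range).
#' @param desat_rate inserted desaturations per hour of sleep.
#' @param desat_depth desaturation depth, SpO2 percentage points (>= 0).
#' @param desat_dur_range desaturation duration range, s.
#' @param spo2_baseline resting SpO2, percent.
#' @param breath_params named list (`WAKE`, `NREM`, `REM`), each with tidal
#'   volume `vt` (mL), respiratory rate `rr` (breaths/min), inspiratory duty
#'   cycle `dc`, and `ifl_frac`, the fraction of flow-limited breaths.
#' @param hvr_params list with `ve_normoxia`/`ve_hypoxia` (mL/min/g) and
#'   `spo2_normoxia`/`spo2_hypoxia` (percent, in (0, 100]).
#' @param body_weight_g body weight, g.
#' @param noise_sd named list of additive channel noise SDs (physical units).
#' @param seed integer seed; mandatory source of all randomness.
#' @return an object of class `"cr_preset"`.
#' @export
synth_preset <- function(name,
                         duration_h = 48,
                         map_light = 134.9, map_dark = 137.5,
                         pulse_pressure = 40,
                         bp_circadian_amplitude = 5, bp_animal_sd = 7,
                         hr_mean = 600,
                         hr_modulations = list(c(1.0, 0.03), c(2.5, 0.02)),
                         sleep_frac = 0.542, nrem_frac_of_sleep = 0.885,
                         mean_bout_s = c(NREM = 150, REM = 80),
                         apnea_rate = 31.4, apnea_cycles_range = c(3L, 5L),
                         desat_rate = 8.4, desat_depth = 6.5,
                         desat_dur_range = c(20, 60), spo2_baseline = 97,
                         breath_params = list(
                           WAKE = list(vt = 0.35, rr = 150, dc = 0.35,
                                       ifl_frac = 0),
                           NREM = list(vt = 0.3, rr = 107.5, dc = 0.3,
                                       ifl_frac = 0.048),
                           REM = list(vt = 0.3, rr = 122.7, dc = 0.35,
                                      ifl_frac = 0.183)),
                         hvr_params = list(ve_normoxia = 1.2,
                                           ve_hypoxia = 2.9,
                                           spo2_normoxia = 97,
                                           spo2_hypoxia = 63),
                         body_weight_g = 45.6,
                         noise_sd = list(pressure = 1, hr = 2, flow = 0.02,
                                         eeg = 15, emg = 0.2, spo2 = 0.15),
                         seed = 1L) {
  stopifnot(duration_h > 0, pulse_pressure >= 0, hr_mean > 0,
            body_weight_g > 0, spo2_baseline > 0, spo2_baseline <= 100)
  if (apnea_rate < 0) stop("apnea_rate must be non-negative")
  if (desat_rate < 0) stop("desat_rate must be non-negative")
  if (desat_depth < 0) stop("desat_depth must be non-negative")
  if (sleep_frac <= 0 || sleep_frac >= 1 ||
      nrem_frac_of_sleep <= 0 || nrem_frac_of_sleep > 1)
    stop("stage fractions must define a proper partition")
  for (m in hr_modulations) {
    if (length(m) != 2 || m[1] <= 0)
      stop("hr_modulations entries must be c(frequency_hz, depth)")
    if (m[2] >= 1)
      stop("modulation depth >= 1 would produce non-positive beat intervals")
  }
  for (st in c("WAKE", "NREM", "REM")) {
    bp <- breath_params[[st]]
    if (is.null(bp) || bp$vt <= 0 || bp$rr <= 0 || bp$dc <= 0 || bp$dc >= 1)
      stop("breath_params$", st, " must have vt > 0, rr > 0, 0 < dc < 1")
  }
  with(hvr_params, {
    if (spo2_normoxia <= 0 || spo2_normoxia > 100 ||
        spo2_hypoxia <= 0 || spo2_hypoxia > 100)
      stop("hvr_params SpO2 values must lie in (0, 100]")
    if (ve_normoxia <= 0 || ve_hypoxia <= 0)
      stop("hvr_params ventilation values must be positive")
  })
  if (is.null(seed)) stop("presets require an explicit seed")
  structure(
    list(name = name, duration_h = duration_h,
         map_light = map_light, map_dark = map_dark,
         pulse_pressure = pulse_pressure,
         bp_circadian_amplitude = bp_circadian_amplitude,
         bp_animal_sd = bp_animal_sd,
         hr_mean = hr_mean, hr_modulations = hr_modulations,
         sleep_frac = sleep_frac, nrem_frac_of_sleep = nrem_frac_of_sleep,
         mean_bout_s = mean_bout_s,
         apnea_rate = apnea_rate, apnea_cycles_range = apnea_cycles_range,
         desat_rate = desat_rate, desat_depth = desat_depth,
         desat_dur_range = desat_dur_range, spo2_baseline = spo2_baseline,
         breath_params = breath_params, hvr_params = hvr_params,
         body_weight_g = body_weight_g, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cr_preset")
}

#' @export
print.cr_preset <- function(x, ...) {
  cat(sprintf(paste0("<cr_preset '%s'> MAP light/dark %.1f/%.1f mmHg, ",
                     "HR %g bpm, BW %.1f g, apneas %.1f/h, seed %d\n"),
              x$name, x$map_light, x$map_dark, x$hr_mean, x$body_weight_g,
              x$apnea_rate, x$seed))
  invisible(x)
}

#' Untreated hypertensive-obese baseline preset
#'
#' Encodes the untreated (control-peptide) NZO study condition: light-phase
#' MAP 134.9 mmHg and dark-phase MAP 137.5 mmHg; sleep architecture with
#' total sleep time 54.2% of the 6-h recording, 88.5% of it NREM (about
#' 22 min REM); NREM breathing with tidal volume 0.3 mL at 107.5 breaths/min
#' and duty cycle 0.3; apneas inserted at 31.4 events/h of sleep and
#' desaturations at 8.4/h; normoxic ventilation 1.2 and hypoxic ventilation
#' 2.9 mL/min/g with saturation falling from 97% to 63% (slope
#' 0.05 mL/min/g per % SpO2); body weight 45.6 g.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [synth_preset()].
#' @return a `"cr_preset"`.
#' @export
preset_nzo_baseline <- function(seed = 20260101L, ...) {
  synth_preset("nzo-baseline", seed = seed, ...)
}

#' Leptin-receptor-blocker-treated preset
#'
#' The treated condition: light-phase MAP reduced to 124.9 mmHg (dark phase
#' 127.9 mmHg), slightly lower body weight (42.4 g), hypoxic ventilation
#' 3.0 mL/min/g; all other parameters shared with the baseline preset.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [synth_preset()].
#' @return a `"cr_preset"`.
#' @export
preset_alloaca_treated <- function(seed = 20260102L, ...) {
  synth_preset("alloaca-treated", map_light = 124.9, map_dark = 127.9,
               body_weight_g = 42.4,
               hvr_params = list(ve_normoxia = 1.2, ve_hypoxia = 3.0,
                                 spo2_normoxia = 97, spo2_hypoxia = 63),
               seed = seed, ...)
}

#' Write a preset to a YAML config file
#' @param preset a `"cr_preset"`.
#' @param path output `.yaml` path.
#' @export
write_preset <- function(preset, path) {
  yaml::write_yaml(unclass(preset), path)
  invisible(path)
}

#' Read a preset from a YAML config file
#' @param path a file written by [write_preset()].
#' @return a `"cr_preset"`.
#' @export
read_preset <- function(path) {
  p <- yaml::read_yaml(path)
  p$mean_bout_s <- unlist(p$mean_bout_s)
  p$hr_modulations <- lapply(p$hr_modulations, unlist)
  p$apnea_cycles_range <- unlist(p$apnea_cycles_range)
  p$desat_dur_range <- unlist(p$desat_dur_range)
  do.call(synth_preset, p)
}
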