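#' Detector and scoring configuration
#'
#' Central registry of the tunable thresholds used by the scoring pipelines.
#' Defaults encode the study's printed rules where the source states them
#' (heart-rate artifact bounds, spectral bands, apnea and desaturation
#' criteria, 10-s epochs) and the package's documented operationalizations
#' where it does not (IFL thresholds, desaturation baseline window and
#' recovery hysteresis, sleep-staging ratios).
#'
#' @param ... named overrides of any default listed below.
#' @return a named list of configuration values.
#' @section Values:
#' \describe{
#'   \item{hr_min_bpm, hr_max_bpm}{valid heart-rate range; readings strictly
#'     outside `[200, 800]` bpm are treated as artifacts.}
#'   \item{lf_band, hf_band}{LF `[0.4, 1.5]` Hz and HF `[1.6, 4.0]` Hz band
#'     limits for beat-interval spectra (band membership is resolved on the
#'     0.1 Hz bin grid, edges inclusive).}
#'   \item{hrv_win_s, hrv_step_s}{2-min windows with 1-min overlap.}
#'   \item{psd_bin_hz}{0.1 Hz spectral aggregation grid.}
#'   \item{breath_ttot_range_s}{physiological gate on cycle duration,
#'     `[0.1, 2]` s (30-600 breaths/min); cycles outside are artifacts.}
#'   \item{breath_hysteresis_frac}{zero-crossing hysteresis, fraction of
#'     running flow amplitude (0.02).}
#'   \item{breath_smooth_s}{low-pass moving-average width before crossing
#'     detection (0.01 s).}
#'   \item{ifl_reach_frac, ifl_early_frac, ifl_run_frac, ifl_effort_rise}{IFL
#'     rule: flow reaches `ifl_reach_frac` (0.95) of V_Imax within the first
#'     `ifl_early_frac` (0.40) of Ti, stays within 5% of that plateau for a
#'     contiguous `ifl_run_frac` (0.40) of Ti, and effort rises by at least
#'     `ifl_effort_rise` (0.05) across the plateau.}
#'   \item{apnea_amp_frac}{breath amplitude at or below this fraction of the
#'     rolling baseline opens an apnea event (0.10, i.e. >=90% reduction).}
#'   \item{apnea_min_dur_s}{absolute apnea duration criterion (0.7 s).}
#'   \item{apnea_n_cycles}{relative duration criterion: 2 local breath
#'     cycles.}
#'   \item{apnea_baseline_n}{breaths in the rolling baseline median (10).}
#'   \item{desat_depth}{SpO2 drop from baseline that scores a desaturation
#'     (5 percentage points).}
#'   \item{desat_recovery}{event closes when SpO2 recovers to within this
#'     many points of baseline (2).}
#'   \item{desat_baseline_s}{trailing rolling-median window for the SpO2
#'     baseline (60 s).}
#'   \item{desat_rate_hz}{SpO2 is decimated to at most this rate before
#'     event detection (5 Hz; desaturations evolve over tens of seconds).}
#'   \item{epoch_s}{sleep-staging epoch length (10 s).}
#'   \item{eeg_delta_band, eeg_theta_band}{EEG bands used by the staging
#'     rule: 2-5 Hz (NREM-dominant) and 5-10 Hz (REM-dominant).}
#'   \item{stage_ratio_delta, stage_ratio_theta}{minimum band-power ratios
#'     for NREM and REM calls (1.5).}
#'   \item{nrem_window_s, nrem_block_min}{20-s NREM analysis subsample, one
#'     per 30-min block.}
#' }
#' @export
cr_config <- function(...) {
  cfg <- list(
    hr_min_bpm = 200, hr_max_bpm = 800,
    lf_band = c(0.4, 1.5), hf_band = c(1.6, 4.0),
    hrv_win_s = 120, hrv_step_s = 60, psd_bin_hz = 0.1,
    breath_ttot_range_s = c(0.1, 2),
    breath_hysteresis_frac = 0.02, breath_smooth_s = 0.01,
    ifl_reach_frac = 0.95, ifl_early_frac = 0.40, ifl_run_frac = 0.40,
    ifl_plateau_tol = 0.05, ifl_effort_rise = 0.05,
    apnea_amp_frac = 0.10, apnea_min_dur_s = 0.7, apnea_n_cycles = 2,
    apnea_baseline_n = 10,
    desat_depth = 5, desat_recovery = 2, desat_baseline_s = 60,
    desat_rate_hz = 5,
    epoch_s = 10,
    eeg_delta_band = c(2, 5), eeg_theta_band = c(5, 10),
    stage_ratio_delta = 1.5, stage_ratio_theta = 1.5,
    nrem_window_s = 20, nrem_block_min = 30
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config entries: ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}
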