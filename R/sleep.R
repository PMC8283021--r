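# Epoch-based sleep staging, sleep architecture, analysis-window selection,
# and scoring of apneas and oxygen desaturations.

#' Hypnogram: per-epoch sleep-stage labels
#'
#' @param stages character vector of `"WAKE"`, `"NREM"`, `"REM"` labels,
#'   one per epoch.
#' @param epoch_s epoch length in seconds (default 10).
#' @param start_clock clock hour of the first epoch.
#' @return an object of class `"cr_hypnogram"`.
#' @export
hypnogram <- function(stages, epoch_s = 10, start_clock = 10) {
  stages <- as.character(stages)
  if (!all(stages %in% c("WAKE", "NREM", "REM")))
    stop("stages must be WAKE, NREM or REM")
  structure(stages, epoch_s = epoch_s, start_clock = start_clock,
            class = "cr_hypnogram")
}

#' @export
print.cr_hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = c("WAKE", "NREM", "REM")))
  cat(sprintf("<cr_hypnogram> %d x %g-s epochs (W %d / N %d / R %d)\n",
              length(x), attr(x, "epoch_s"), tab[1], tab[2], tab[3]))
  invisible(x)
}

stages_of <- function(hyp) as.character(unclass(hyp))

stage_at <- function(hyp, time_s) {
  ep <- pmin(length(hyp), pmax(1L, floor(time_s / attr(hyp, "epoch_s")) + 1L))
  stages_of(hyp)[ep]
}

# Per-epoch EEG band powers and EMG RMS, vectorized over epochs via mvfft.
epoch_features <- function(eeg, emg, config) {
  epoch_s <- config$epoch_s
  n_ep <- floor(trace_duration(eeg) / epoch_s)
  n_ep_m <- floor(trace_duration(emg) / epoch_s)
  if (n_ep != n_ep_m)
    stop("EEG and EMG cover different numbers of epochs (", n_ep, " vs ",
         n_ep_m, ")")
  if (n_ep < 1L) stop("recording shorter than one epoch")
  spe <- as.integer(round(epoch_s * eeg$rate))
  x <- matrix(eeg$values[seq_len(n_ep * spe)], nrow = spe)
  x <- sweep(x, 2, colMeans(x))
  P <- Mod(stats::mvfft(x))^2
  freq <- (seq_len(spe) - 1L) * eeg$rate / spe
  band_power <- function(band) {
    sel <- freq >= band[1] & freq < band[2]
    colSums(P[sel, , drop = FALSE])
  }
  spm <- as.integer(round(epoch_s * emg$rate))
  m <- matrix(emg$values[seq_len(n_ep * spm)], nrow = spm)
  list(n_ep = n_ep,
       p_delta = band_power(config$eeg_delta_band),
       p_theta = band_power(config$eeg_theta_band),
       rms = sqrt(colMeans(m^2)))
}

#' Score sleep stages in 10-s epochs from EEG and EMG
#'
#' Deterministic operationalization of the visual staging criteria: per
#' epoch, the EEG power in the 2-5 Hz and 5-10 Hz bands and the EMG RMS
#' are computed; an epoch is REM when 5-10 Hz power dominates
#' (`p(5-10)/p(2-5) > stage_ratio_theta`) under muscle atonia
#' (`RMS < theta_atonia`), NREM when 2-5 Hz power dominates under low tonus
#' (`RMS < theta_m`), and WAKE otherwise. The EMG thresholds are calibrated
#' per recording from its own log-RMS percentile distribution unless given
#' explicitly.
#'
#' @param eeg,emg aligned [trace()]s covering the same number of epochs.
#' @param config a [cr_config()].
#' @param thresholds optional list with `theta_m` and `theta_atonia`
#'   (EMG units) overriding the per-recording calibration.
#' @return a [hypnogram()].
#' @export
score_epochs <- function(eeg, emg, config = cr_config(), thresholds = NULL) {
  f <- epoch_features(eeg, emg, config)
  if (is.null(thresholds)) {
    logr <- log(pmax(f$rms, 1e-12))
    theta_m <- exp(mean(stats::quantile(logr, c(0.25, 0.75), names = FALSE)))
    theta_atonia <- exp(mean(stats::quantile(logr, c(0.01, 0.35),
                                             names = FALSE)))
    if (theta_atonia >= theta_m) theta_atonia <- theta_m / 3
  } else {
    theta_m <- thresholds$theta_m
    theta_atonia <- thresholds$theta_atonia
  }
  ratio_t <- f$p_theta / pmax(f$p_delta, 1e-300)
  ratio_d <- f$p_delta / pmax(f$p_theta, 1e-300)
  stages <- rep("WAKE", f$n_ep)
  stages[ratio_d > config$stage_ratio_delta & f$rms < theta_m] <- "NREM"
  stages[ratio_t > config$stage_ratio_theta & f$rms < theta_atonia] <- "REM"
  hypnogram(stages, config$epoch_s, eeg$start_clock)
}

#' Sleep architecture summary
#'
#' Total sleep time is the summed duration of NREM and REM epochs; stage
#' percentages are fractions of TST; efficiency is TST over recording
#' duration.
#'
#' @param hyp a [hypnogram()].
#' @param recording_duration_s denominator for sleep efficiency (defaults
#'   to the hypnogram duration).
#' @return an object of class `"cr_sleep_arch"`: `tst_min`, `pct_nrem`,
#'   `pct_rem`, `efficiency_pct`, `no_sleep` flag.
#' @export
architecture <- function(hyp,
                         recording_duration_s =
                           length(hyp) * attr(hyp, "epoch_s")) {
  epoch_s <- attr(hyp, "epoch_s")
  st <- stages_of(hyp)
  n_n <- sum(st == "NREM"); n_r <- sum(st == "REM")
  tst_min <- epoch_s * (n_n + n_r) / 60
  no_sleep <- (n_n + n_r) == 0L
  structure(
    list(tst_min = tst_min,
         pct_nrem = if (no_sleep) NA_real_ else 100 * n_n / (n_n + n_r),
         pct_rem = if (no_sleep) NA_real_ else 100 * n_r / (n_n + n_r),
         efficiency_pct = 100 * tst_min * 60 / recording_duration_s,
         no_sleep = no_sleep),
    class = "cr_sleep_arch")
}

#' @export
print.cr_sleep_arch <- function(x, ...) {
  cat(sprintf("<cr_sleep_arch> TST %.1f min, NREM %.1f%%, REM %.1f%%, efficiency %.1f%%\n",
              x$tst_min, x$pct_nrem, x$pct_rem, x$efficiency_pct))
  invisible(x)
}

#' Select ventilation analysis windows from a hypnogram
#'
#' All REM epochs are returned as REM windows (one per contiguous REM run).
#' NREM breathing is subsampled: within each successive 30-min block, the
#' first run of at least two consecutive NREM epochs contributes one 20-s
#' window (automating the study design's one manual subsample per 30 min).
#'
#' @param hyp a [hypnogram()].
#' @param config a [cr_config()].
#' @return `data.frame` with `type` (`"REM"`/`"NREM"`), `start_s`,
#'   `duration_s`.
#' @export
select_analysis_windows <- function(hyp, config = cr_config()) {
  epoch_s <- attr(hyp, "epoch_s")
  st <- stages_of(hyp)
  runs <- rle(st)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  rem <- which(runs$values == "REM")
  out <- data.frame(type = character(0), start_s = numeric(0),
                    duration_s = numeric(0))
  if (length(rem))
    out <- data.frame(type = "REM", start_s = starts[rem] * epoch_s,
                      duration_s = runs$lengths[rem] * epoch_s)
  ep_per_block <- as.integer(config$nrem_block_min * 60 / epoch_s)
  need <- as.integer(ceiling(config$nrem_window_s / epoch_s))
  n_blocks <- ceiling(length(st) / ep_per_block)
  for (b in seq_len(n_blocks)) {
    lo <- (b - 1L) * ep_per_block + 1L
    hi <- min(length(st), b * ep_per_block)
    r <- rle(st[lo:hi] == "NREM")
    e <- cumsum(r$lengths)
    cand <- which(r$values & r$lengths >= need)
    if (!length(cand)) next
    first <- cand[1]
    start_ep <- lo - 1L + e[first] - r$lengths[first]
    out <- rbind(out, data.frame(type = "NREM",
                                 start_s = start_ep * epoch_s,
                                 duration_s = config$nrem_window_s))
  }
  out[order(out$start_s), , drop = FALSE]
}

empty_events <- function() {
  structure(data.frame(type = character(0), start_s = numeric(0),
                       duration_s = numeric(0), stage = character(0)),
            class = c("cr_events", "data.frame"))
}

#' Detect apneas in airflow during sleep
#'
#' A rolling baseline amplitude (median V_Imax of the preceding 10 breaths)
#' tracks normal breathing; a candidate event opens over a run of breaths
#' whose amplitude is at or below 10% of that baseline (a >= 90%
#' reduction). The run is scored as an apnea when its duration reaches
#' 0.7 s or spans two local breath cycles (twice the median recent Ttot),
#' whichever criterion is satisfied. Events whose onset falls in a WAKE
#' epoch are discarded.
#'
#' @param flow airflow [trace()].
#' @param hyp a [hypnogram()] aligned with the flow trace.
#' @param config a [cr_config()].
#' @param breaths optional precomputed [segment_breaths()] table.
#' @return a `"cr_events"` data.frame (`type = "APNEA"`, `start_s`,
#'   `duration_s`, `stage`).
#' @export
detect_apneas <- function(flow, hyp, config = cr_config(), breaths = NULL) {
  if (all(stages_of(hyp) == "WAKE")) {
    warning("no sleep epochs; no apneas scored")
    return(empty_events())
  }
  if (is.null(breaths)) breaths <- segment_breaths(flow, config)
  nb <- nrow(breaths)
  if (nb == 0L) return(empty_events())
  n_base <- config$apnea_baseline_n
  roll_med <- function(x) {
    r <- data.table::frollapply(x, n_base, stats::median, align = "right")
    c(NA_real_, r[-length(r)])         # preceding breaths only
  }
  baseline <- roll_med(breaths$V_Imax)
  recent_ttot <- roll_med(breaths$Ttot)
  small <- !is.na(baseline) & breaths$V_Imax <= config$apnea_amp_frac * baseline
  if (!any(small)) return(empty_events())
  # the hysteresis crossing fires late on a near-silent breath; back the
  # event start up to the true zero crossing so durations are not clipped
  sm <- moving_average(flow$values, round(flow$rate * config$breath_smooth_s))
  refine_start <- function(i_on) {
    j <- i_on
    lim <- max(1L, i_on - as.integer(2 * flow$rate))
    while (j > lim && sm[j - 1L] > 0) j <- j - 1L
    (j - 1L) / flow$rate
  }
  r <- rle(small)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    start_s <- refine_start(breaths$i_on[i0])
    dur <- breaths$onset[i1] + breaths$Ttot[i1] - start_s
    two_cycles <- config$apnea_n_cycles * recent_ttot[i0]
    tol <- 1 / (attr(breaths, "rate") %||% Inf)   # crossing quantization
    if (!(dur >= config$apnea_min_dur_s - tol ||
          (is.finite(two_cycles) && dur >= two_cycles - tol))) next
    st <- stage_at(hyp, start_s)
    if (st == "WAKE") next
    ev[[length(ev) + 1L]] <- data.frame(type = "APNEA", start_s = start_s,
                                        duration_s = dur, stage = st)
  }
  if (!length(ev)) return(empty_events())
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  structure(out, class = c("cr_events", "data.frame"))
}

#' Apnea index: events per hour of total sleep time
#'
#' @param events a `"cr_events"` table (APNEA rows are counted).
#' @param arch a [architecture()] summary supplying TST.
#' @return events/h, or `NA` (with attribute `"undefined"`) when TST is 0.
#' @export
apnea_index <- function(events, arch) {
  n <- sum(events$type == "APNEA")
  if (arch$tst_min <= 0)
    return(structure(NA_real_, undefined = TRUE))
  n / (arch$tst_min / 60)
}

#' Score oxygen desaturations and the desaturation index
#'
#' The SpO2 baseline is a trailing 60-s rolling median (the channel is
#' first decimated to at most 5 Hz; desaturations evolve over tens of
#' seconds). An event opens when SpO2 falls at least `desat_depth` (5)
#' percentage points below baseline and closes when it recovers to within
#' `desat_recovery` (2) points. Events with onset in WAKE are discarded.
#' ODI divides the event count by total sleep time; mean SpO2 is reported
#' separately over NREM and REM epochs.
#'
#' @param spo2 SpO2 [trace()] in percent, values in (0, 100].
#' @param hyp a [hypnogram()] aligned with the trace.
#' @param config a [cr_config()].
#' @return list with `events` (`"cr_events"`), `odi` (events/h),
#'   `mean_spo2` (named vector, NREM/REM).
#' @export
desaturation_events <- function(spo2, hyp, config = cr_config()) {
  v <- spo2$values
  if (any(v <= 0 | v > 100)) stop("SpO2 values must lie in (0, 100]")
  tr <- spo2
  if (tr$rate > config$desat_rate_hz) tr <- resample(tr, config$desat_rate_hz)
  x <- tr$values
  w <- min(length(x), as.integer(round(config$desat_baseline_s * tr$rate)))
  base <- data.table::frollapply(x, w, stats::median, align = "right")
  first_ok <- which(!is.na(base))[1]
  base[seq_len(first_ok - 1L)] <- base[first_ok]
  delta <- base - x

  open <- delta >= config$desat_depth
  close <- delta <= config$desat_recovery
  ev <- list()
  state <- FALSE
  t0 <- NA_real_
  tt <- (seq_along(x) - 1L) / tr$rate
  for (i in seq_along(x)) {
    if (!state && open[i]) {
      state <- TRUE; t0 <- tt[i]
    } else if (state && close[i]) {
      state <- FALSE
      ev[[length(ev) + 1L]] <- c(t0, tt[i] - t0)
    }
  }
  if (state) ev[[length(ev) + 1L]] <- c(t0, tt[length(x)] - t0)

  events <- empty_events()
  if (length(ev)) {
    m <- do.call(rbind, ev)
    st <- stage_at(hyp, m[, 1])
    keep <- st != "WAKE"
    if (any(keep))
      events <- structure(
        data.frame(type = "DESAT", start_s = m[keep, 1],
                   duration_s = m[keep, 2], stage = st[keep]),
        class = c("cr_events", "data.frame"))
  }
  arch <- architecture(hyp)
  odi <- if (arch$tst_min <= 0) structure(NA_real_, undefined = TRUE) else
    nrow(events) / (arch$tst_min / 60)

  ep <- pmin(length(hyp), floor(trace_time(spo2) /
                                  attr(hyp, "epoch_s")) + 1L)
  st_s <- stages_of(hyp)[ep]
  mean_spo2 <- c(NREM = mean(v[st_s == "NREM"]), REM = mean(v[st_s == "REM"]))
  list(events = events, odi = odi, mean_spo2 = mean_spo2)
}
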