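# Heart-rate-variability spectral analysis of the beat-interval series:
# artifact filtering -> 60/HR -> overlapping Hamming-windowed 2-min
# segments -> periodogram aggregated on a 0.1 Hz grid -> LF/HF band powers.

#' Filter heart-rate artifacts
#'
#' Readings strictly below `hr_min_bpm` (200) or strictly above
#' `hr_max_bpm` (800) are treated as artifacts and replaced by linear
#' interpolation between the nearest valid neighbours; invalid runs at the
#' edges take the nearest valid value.
#'
#' @param hr heart-rate [trace()] in bpm.
#' @param config a [cr_config()].
#' @return a [trace()] with artifacts imputed.
#' @export
filter_hr_artifacts <- function(hr, config = cr_config()) {
  v <- hr$values
  bad <- !is.finite(v) | v < config$hr_min_bpm | v > config$hr_max_bpm |
    !hr$valid
  if (all(bad)) stop("no valid heart-rate samples")
  if (any(bad)) {
    idx <- which(!bad)
    v <- if (length(idx) == 1L) rep(v[idx], length(v)) else
      stats::approx(idx, v[idx], xout = seq_along(v), method = "linear",
                    rule = 2)$y
  }
  trace(v, hr$rate, hr$label, hr$units, hr$start_clock)
}

#' Convert heart rate to the beat-to-beat interval series
#'
#' The reciprocal of the instantaneous heart rate estimates the beat
#' interval: `interval_s = 60 / hr_bpm`, sample-wise, preserving rate and
#' timing.
#'
#' @param hr heart-rate [trace()] in bpm; all values must be positive
#'   (artifact-filter first).
#' @return interval [trace()] in seconds.
#' @export
to_beat_interval <- function(hr) {
  if (any(hr$values <= 0))
    stop("non-positive heart-rate samples; apply filter_hr_artifacts() first")
  trace(60 / hr$values, hr$rate, "beat_interval", "s", hr$start_clock)
}

#' Split a trace into overlapping mean-removed Hamming-windowed segments
#'
#' @param tr a [trace()], duration at least `win_s`.
#' @param win_s,step_s window length and hop in seconds (defaults 120/60:
#'   2-min segments overlapping by 1 min).
#' @return list of numeric vectors (windowed segments), with the sampling
#'   rate attached as attribute `"rate"` on each.
#' @export
segment_windows <- function(tr, win_s = 120, step_s = 60) {
  n_win <- as.integer(round(win_s * tr$rate))
  n_step <- as.integer(round(step_s * tr$rate))
  total_s <- trace_duration(tr)
  if (total_s < win_s) stop("trace shorter than one window (", win_s, " s)")
  n_seg <- floor((total_s - win_s) / step_s) + 1
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_win) - 1L) / (n_win - 1L))
  lapply(seq_len(n_seg), function(k) {
    x <- tr$values[(k - 1L) * n_step + seq_len(n_win)]
    seg <- (x - mean(x)) * w
    attr(seg, "rate") <- tr$rate
    attr(seg, "window") <- w
    seg
  })
}

#' Binned power spectral density of one windowed segment
#'
#' One-sided periodogram of the (already mean-removed, Hamming-windowed)
#' segment, normalized so that total power equals signal variance
#' compensated for the window (`power_k = 2|X_k|^2 / (N * sum(w^2))`), then
#' aggregated into contiguous 0.1 Hz bins centered on the 0.1 Hz grid
#' (`[k*0.1 - 0.05, k*0.1 + 0.05)`) by summing raw-bin power, so a
#' modulation at a grid frequency falls in the middle of its bin. Binned
#' total power equals raw total power exactly.
#'
#' @param segment a segment from [segment_windows()] (or any numeric vector
#'   with a `"rate"` attribute / explicit `rate`).
#' @param rate sampling rate in Hz.
#' @param bin_hz aggregation grid (default 0.1 Hz).
#' @return `data.frame` with `bin_lo`, `center` (Hz) and `power` (signal
#'   units squared), plus attribute `"raw_total"`.
#' @export
psd_binned <- function(segment, rate = attr(segment, "rate"), bin_hz = 0.1) {
  if (is.null(rate)) stop("sampling rate not supplied")
  n <- length(segment)
  w <- attr(segment, "window") %||% rep(1, n)
  X <- stats::fft(as.numeric(segment))
  kmax <- floor(n / 2)
  freq <- (1:kmax) * rate / n
  pw <- 2 * Mod(X[2:(kmax + 1L)])^2 / (n * sum(w^2))
  bin <- as.integer(round(freq / bin_hz))
  agg <- rowsum(pw, bin)
  bins <- as.integer(rownames(agg))
  out <- data.frame(bin_lo = bins * bin_hz - bin_hz / 2,
                    center = bins * bin_hz,
                    power = as.numeric(agg))
  attr(out, "raw_total") <- sum(pw)
  attr(out, "bin_hz") <- bin_hz
  out
}

#' LF/HF band powers and their ratio across segments
#'
#' Per segment, LF is the summed power of the bins whose centers lie in
#' 0.4-1.5 Hz and HF of those with centers in 1.6-4.0 Hz, both edges
#' inclusive (so a modulation at exactly 1.5 Hz counts as LF and one at
#' 1.6 Hz as HF). Band powers are averaged across segments and the LF/HF
#' ratio is taken on the averages. A zero average HF flags the ratio as
#' undefined rather than returning infinity.
#'
#' @param psd_list list of [psd_binned()] tables (>= 1).
#' @param config a [cr_config()] (band limits).
#' @return an object of class `"cr_hrv"`: list with `lf`, `hf` (signal
#'   units squared), `lf_ms2`, `hf_ms2` (interval power in ms^2),
#'   `lf_hf_ratio`, `hf_zero` flag, `n_segments`, and per-segment values.
#' @export
band_powers <- function(psd_list, config = cr_config()) {
  if (length(psd_list) == 0L) stop("no segments supplied")
  in_band <- function(psd, band) {
    sel <- psd$center >= band[1] - 1e-9 & psd$center <= band[2] + 1e-9
    sum(psd$power[sel])
  }
  lf_seg <- vapply(psd_list, in_band, 0, band = config$lf_band)
  hf_seg <- vapply(psd_list, in_band, 0, band = config$hf_band)
  lf <- mean(lf_seg); hf <- mean(hf_seg)
  hf_zero <- hf <= 0
  structure(
    list(lf = lf, hf = hf, lf_ms2 = lf * 1e6, hf_ms2 = hf * 1e6,
         lf_hf_ratio = if (hf_zero) NA_real_ else lf / hf,
         hf_zero = hf_zero, n_segments = length(psd_list),
         lf_per_segment = lf_seg, hf_per_segment = hf_seg),
    class = "cr_hrv")
}

#' @export
print.cr_hrv <- function(x, ...) {
  cat(sprintf("<cr_hrv> LF %.4g ms^2, HF %.4g ms^2, LF/HF %s (%d segments)\n",
              x$lf_ms2, x$hf_ms2,
              if (x$hf_zero) "undefined (HF = 0)" else
                sprintf("%.3f", x$lf_hf_ratio),
              x$n_segments))
  invisible(x)
}

#' Full heart-rate-variability spectral pipeline
#'
#' Chains [filter_hr_artifacts()], [to_beat_interval()], downsampling to
#' `analysis_rate` (default 20 Hz, comfortably above twice the 4 Hz band
#' ceiling), [segment_windows()], [psd_binned()] and [band_powers()].
#'
#' @param hr heart-rate [trace()] in bpm.
#' @param config a [cr_config()].
#' @param analysis_rate rate at which the interval series is analyzed.
#' @return a `"cr_hrv"` summary (see [band_powers()]).
#' @export
hrv_spectral <- function(hr, config = cr_config(), analysis_rate = 20) {
  iv <- to_beat_interval(filter_hr_artifacts(hr, config))
  if (iv$rate > analysis_rate) iv <- resample(iv, analysis_rate)
  segs <- segment_windows(iv, config$hrv_win_s, config$hrv_step_s)
  band_powers(lapply(segs, psd_binned, bin_hz = config$psd_bin_hz), config)
}
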