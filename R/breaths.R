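# Breath segmentation and per-breath plethysmography metrics.

#' Segment calibrated airflow into breaths
#'
#' Breath onsets are negative-to-positive zero crossings of the low-pass
#' smoothed flow with a hysteresis of 2% of the running flow amplitude
#' (suppressing noise-triggered micro-breaths). Per breath: `Ti` is the
#' duration of the positive (inspiratory) lobe, `V_T` the integral of flow
#' over it, `V_Imax` its maximum, `MIFR = V_T/Ti`, `DC = Ti/Ttot`,
#' `RR = 60/Ttot` and instantaneous `V_E = V_T * RR`. Cycles with `Ttot`
#' outside the physiological gate (0.1-2 s, i.e. 30-600 breaths/min) are
#' rejected as artifacts.
#'
#' @param flow airflow [trace()] in mL/s, inspiration positive,
#'   rate >= 100 Hz.
#' @param config a [cr_config()].
#' @return a `data.frame` of class `"cr_breaths"` with one row per breath:
#'   `onset`, `Ti`, `Ttot`, `V_T`, `V_Imax`, `MIFR`, `DC`, `RR`, `VE_inst`,
#'   `ifl` (NA until [detect_ifl()]), plus sample indices `i_on`, `i_end`.
#' @export
segment_breaths <- function(flow, config = cr_config()) {
  if (flow$rate < 100) stop("breath segmentation requires rate >= 100 Hz")
  v <- flow$values
  empty <- structure(
    data.frame(onset = numeric(0), Ti = numeric(0), Ttot = numeric(0),
               V_T = numeric(0), V_Imax = numeric(0), MIFR = numeric(0),
               DC = numeric(0), RR = numeric(0), VE_inst = numeric(0),
               ifl = logical(0), i_on = integer(0), i_end = integer(0)),
    class = c("cr_breaths", "data.frame"), rate = flow$rate,
    duration_s = trace_duration(flow))
  amp <- stats::quantile(abs(v), 0.95, names = FALSE)
  if (amp <= 0) return(empty)
  s <- moving_average(v, round(flow$rate * config$breath_smooth_s))
  h <- config$breath_hysteresis_frac * amp

  # hysteresis state: +1 after exceeding +h, -1 after dropping below -h
  st <- integer(length(s))
  st[s >= h] <- 1L
  st[s <= -h] <- -1L
  nz <- st != 0L
  cs <- cumsum(nz)
  filled <- ifelse(cs > 0L, st[nz][pmax(cs, 1L)], 0L)
  onsets <- which(filled == 1L & c(0L, filled[-length(filled)]) == -1L)
  if (length(onsets) < 2L) return(empty)

  dtime <- 1 / flow$rate
  out <- vector("list", length(onsets) - 1L)
  for (b in seq_len(length(onsets) - 1L)) {
    i0 <- onsets[b]; i1 <- onsets[b + 1L] - 1L
    ttot <- (i1 - i0 + 1L) * dtime
    if (ttot < config$breath_ttot_range_s[1] ||
        ttot > config$breath_ttot_range_s[2]) next
    seg_state <- filled[i0:i1]
    down <- which(seg_state == -1L)
    n_insp <- if (length(down)) down[1] - 1L else length(seg_state)
    ti <- n_insp * dtime
    if (ti <= 0 || ti >= ttot) next
    insp <- v[i0:(i0 + n_insp - 1L)]
    vt <- sum(insp) * dtime
    # peak flow from the smoothed trace so single-sample noise excursions
    # do not inflate the amplitude of near-silent (apneic) breaths
    out[[b]] <- c(onset = (i0 - 1L) * dtime, Ti = ti, Ttot = ttot,
                  V_T = max(vt, 0), V_Imax = max(s[i0:(i0 + n_insp - 1L)]),
                  i_on = i0, i_end = i1)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  m <- as.data.frame(do.call(rbind, out))
  br <- data.frame(onset = m$onset, Ti = m$Ti, Ttot = m$Ttot, V_T = m$V_T,
                   V_Imax = m$V_Imax, MIFR = m$V_T / m$Ti,
                   DC = m$Ti / m$Ttot, RR = 60 / m$Ttot,
                   VE_inst = m$V_T * 60 / m$Ttot, ifl = NA,
                   i_on = as.integer(m$i_on), i_end = as.integer(m$i_end))
  structure(br, class = c("cr_breaths", "data.frame"), rate = flow$rate,
            duration_s = trace_duration(flow))
}

#' Minute ventilation from a breath table
#'
#' `V_E` is the mean over breaths of the instantaneous minute ventilation
#' `V_T * 60 / Ttot` (mL/min); `V_E_norm` divides by body weight.
#'
#' @param breaths a `"cr_breaths"` table with >= 1 breath.
#' @param body_weight_g body weight in grams (> 0).
#' @return list with `ve_ml_min` and `ve_norm` (mL/min/g).
#' @export
minute_ventilation <- function(breaths, body_weight_g) {
  if (nrow(breaths) == 0L) stop("empty breath table")
  if (body_weight_g <= 0) stop("body weight must be positive")
  ve <- mean(breaths$V_T * 60 / breaths$Ttot)
  list(ve_ml_min = ve, ve_norm = ve / body_weight_g)
}

#' Flag inspiratory flow limitation
#'
#' A breath is flow-limited when its inspiratory profile plateaus early
#' despite rising effort: (a) flow first reaches `ifl_reach_frac` (95%) of
#' `V_Imax` within the first `ifl_early_frac` (40%) of `Ti`; (b) flow stays
#' within `ifl_plateau_tol` (5%) of `V_Imax` for a contiguous run of at
#' least `ifl_run_frac` (40%) of `Ti`; and (c) effort amplitude rises
#' across the plateau (mean over its second half at least
#' `1 + ifl_effort_rise` times the first half). All thresholds live in
#' [cr_config()]. Without an effort channel the flags are set to `NA` with
#' a warning.
#'
#' @param breaths a `"cr_breaths"` table from [segment_breaths()].
#' @param flow the airflow [trace()] the table came from.
#' @param effort aligned respiratory-effort [trace()] (box-pressure
#'   surrogate), or `NULL`.
#' @param config a [cr_config()].
#' @return the breath table with the `ifl` column filled.
#' @export
detect_ifl <- function(breaths, flow, effort = NULL, config = cr_config()) {
  if (nrow(breaths) == 0L) return(breaths)
  if (is.null(effort)) {
    warning("no effort channel; IFL flags set to NA")
    breaths$ifl <- NA
    return(breaths)
  }
  if (abs(effort$rate - flow$rate) > 1e-9)
    effort <- resample(effort, flow$rate)
  v <- flow$values
  ev <- abs(effort$values)
  flags <- logical(nrow(breaths))
  for (b in seq_len(nrow(breaths))) {
    n_insp <- as.integer(round(breaths$Ti[b] * flow$rate))
    i0 <- breaths$i_on[b]
    insp <- v[i0:(i0 + n_insp - 1L)]
    vimax <- max(insp)
    if (vimax <= 0) next
    hi <- insp >= config$ifl_reach_frac * vimax
    first <- which(hi)[1]
    if (is.na(first) || first > config$ifl_early_frac * n_insp) next
    runs <- rle(hi)
    if (max(runs$lengths[runs$values]) < config$ifl_run_frac * n_insp) next
    run_end <- cumsum(runs$lengths)
    k <- which(runs$values & runs$lengths == max(runs$lengths[runs$values]))[1]
    p0 <- run_end[k] - runs$lengths[k] + 1L
    p1 <- run_end[k]
    pe <- ev[(i0 + p0 - 1L):(i0 + p1 - 1L)]
    half <- length(pe) %/% 2L
    if (half < 1L) next
    rise <- mean(pe[(half + 1L):length(pe)]) /
      max(mean(pe[seq_len(half)]), 1e-12)
    flags[b] <- rise >= 1 + config$ifl_effort_rise
  }
  breaths$ifl <- flags
  breaths
}
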