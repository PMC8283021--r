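# Blood-pressure telemetry reduction: waveform -> beats -> hourly means ->
# circadian phase summaries -> group table.

#' Detect beats in an arterial-pressure waveform
#'
#' Per-cycle systolic/diastolic extraction: the lightly smoothed waveform is
#' compared against a 1-s rolling mean (which for a pulsatile signal sits
#' between diastole and systole); each upward crossing opens a cardiac
#' cycle, subject to a refractory period so that no rhythm faster than
#' 800 bpm is admitted. SBP/DBP are the raw extremes within each cycle.
#'
#' @param tr pressure [trace()], rate >= 50 Hz.
#' @param refractory_s minimum beat separation (default 60/800 s).
#' @param min_pulse_mmHg smallest waveform excursion treated as pulsatile;
#'   flatter signals yield an empty beat series with a warning.
#' @return a `data.frame` of class `"cr_beats"` with columns `beat_times`
#'   (s), `sbp`, `dbp` (mmHg), carrying the source duration as an attribute.
#' @export
detect_beats <- function(tr, refractory_s = 60 / 800, min_pulse_mmHg = 1) {
  if (tr$rate < 50) stop("beat detection requires rate >= 50 Hz")
  v_raw <- tr$values
  empty <- function() {
    structure(data.frame(beat_times = numeric(0), sbp = numeric(0),
                         dbp = numeric(0)),
              class = c("cr_beats", "data.frame"),
              duration_s = trace_duration(tr), start_clock = tr$start_clock)
  }
  if (max(v_raw) - min(v_raw) < min_pulse_mmHg) {
    warning("waveform has no pulsatile component; returning no beats")
    return(empty())
  }
  v <- moving_average(v_raw, round(tr$rate * 0.01))
  thr <- data.table::frollmean(v, n = as.integer(max(3, tr$rate)),
                               align = "center")
  thr[is.na(thr)] <- mean(v)
  up <- v > thr
  cross <- which(up & !c(FALSE, up[-length(up)]))
  if (length(cross) < 2L) {
    warning("waveform has no pulsatile component; returning no beats")
    return(empty())
  }
  # refractory: suppress crossings that chase the previous kept one
  keep <- c(TRUE, diff(cross) >= refractory_s * tr$rate)
  cross <- cross[keep]
  if (length(cross) < 2L) return(empty())

  dt <- data.table::data.table(
    v = v_raw, g = findInterval(seq_along(v_raw), cross))
  dt <- dt[dt$g >= 1L & dt$g < length(cross)]
  per <- dt[, list(sbp = max(v), dbp = min(v)), by = "g"]
  data.table::setorderv(per, "g")
  structure(
    data.frame(beat_times = (cross[per$g] - 1L) / tr$rate,
               sbp = per$sbp, dbp = per$dbp),
    class = c("cr_beats", "data.frame"),
    duration_s = trace_duration(tr), start_clock = tr$start_clock)
}

#' Hourly and circadian-phase blood-pressure summary
#'
#' Averages per-beat SBP/DBP into clock-aligned (top-of-hour) hourly bins,
#' derives MAP from the hourly means by the one-third pulse-pressure rule
#' `MAP = DBP + (SBP - DBP)/3`, takes heart rate as beats per minute, and
#' assigns each hour to the light (`[lights_on, lights_on + 12h)`) or dark
#' phase. Hours without beats are kept as missing rows and excluded from
#' phase means; partially covered edge hours are dropped.
#'
#' @param beats a `"cr_beats"` table from [detect_beats()].
#' @param lights_on_hour clock hour of lights-on (default 9).
#' @param start_clock clock hour of the first sample (defaults to the value
#'   recorded by [detect_beats()]).
#' @param duration_s recording duration in seconds (defaults likewise).
#' @return an object of class `"cr_bp_summary"`: list with `hourly`
#'   (hour, clock_hour, phase, sbp, dbp, map, hr, n_beats) and `phase`
#'   (per-phase means of the hourly values).
#' @export
hourly_summary <- function(beats, lights_on_hour = 9,
                           start_clock = attr(beats, "start_clock"),
                           duration_s = attr(beats, "duration_s")) {
  if (is.null(start_clock)) start_clock <- 0
  if (is.null(duration_s)) duration_s <- max(beats$beat_times)
  if (nrow(beats) == 0L || duration_s < 3600 ||
      diff(range(beats$beat_times)) < 3000)
    stop("hourly summary requires at least 1 h of beats")
  abs_s <- start_clock * 3600 + beats$beat_times
  bin <- floor(abs_s / 3600)
  full <- bin * 3600 >= start_clock * 3600 - 1e-6 &
    (bin + 1) * 3600 <= start_clock * 3600 + duration_s + 1e-6
  dtb <- data.table::data.table(bin = bin[full], sbp = beats$sbp[full],
                                dbp = beats$dbp[full])
  agg <- dtb[, list(sbp = mean(sbp), dbp = mean(dbp),
                    n_beats = .N), by = "bin"]
  bins_all <- seq(ceiling(start_clock - 1e-9),
                  floor(start_clock + duration_s / 3600 + 1e-9) - 1L)
  out <- data.frame(bin = bins_all)
  out <- merge(out, as.data.frame(agg), by = "bin", all.x = TRUE)
  out$n_beats[is.na(out$n_beats)] <- 0L
  out$map <- out$dbp + (out$sbp - out$dbp) / 3
  out$hr <- out$n_beats / 60
  out$hr[out$n_beats == 0L] <- NA_real_
  out$clock_hour <- out$bin %% 24
  out$phase <- ifelse(((out$clock_hour - lights_on_hour) %% 24) < 12,
                      "light", "dark")
  hourly <- data.frame(hour = out$bin - out$bin[1], clock_hour = out$clock_hour,
                       phase = out$phase, sbp = out$sbp, dbp = out$dbp,
                       map = out$map, hr = out$hr, n_beats = out$n_beats)
  ok <- hourly$n_beats > 0L
  ph <- do.call(rbind, lapply(c("light", "dark"), function(p) {
    rows <- hourly[ok & hourly$phase == p, ]
    data.frame(phase = p, map = mean(rows$map), sbp = mean(rows$sbp),
               dbp = mean(rows$dbp), hr = mean(rows$hr), n_hours = nrow(rows))
  }))
  structure(list(hourly = hourly, phase = ph), class = "cr_bp_summary")
}

#' @export
print.cr_bp_summary <- function(x, ...) {
  cat("<cr_bp_summary>", nrow(x$hourly), "hourly rows\n")
  print(x$phase, row.names = FALSE)
  invisible(x)
}

#' Per-animal and group blood-pressure table
#'
#' Binds the phase means of several animals into a tidy per-animal table and
#' computes group mean +/- SEM per phase and metric.
#'
#' @param summaries list of `"cr_bp_summary"` objects.
#' @param animal_ids,groups optional vectors parallel to `summaries`
#'   (defaults: `animal1..n`, single group `"all"`).
#' @return list with `per_animal` (animal, group, phase, map, sbp, dbp, hr)
#'   and `group_stats` (group, phase, metric, mean, sem, n).
#' @export
group_bp_table <- function(summaries, animal_ids = NULL, groups = NULL) {
  if (length(summaries) == 0L) stop("no summaries supplied")
  n <- length(summaries)
  if (is.null(animal_ids)) animal_ids <- sprintf("animal%d", seq_len(n))
  if (is.null(groups)) groups <- rep("all", n)
  per <- do.call(rbind, lapply(seq_len(n), function(i) {
    ph <- summaries[[i]]$phase
    data.frame(animal = animal_ids[i], group = groups[i], phase = ph$phase,
               map = ph$map, sbp = ph$sbp, dbp = ph$dbp, hr = ph$hr)
  }))
  long <- do.call(rbind, lapply(c("map", "sbp", "dbp", "hr"), function(m)
    data.frame(group = per$group, phase = per$phase, metric = m,
               value = per[[m]])))
  dtl <- data.table::as.data.table(long)
  gs <- dtl[, list(mean = mean(value), sem = sem(value), n = .N),
            by = c("group", "phase", "metric")]
  list(per_animal = per, group_stats = as.data.frame(gs))
}
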