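#' Uniformly sampled signal trace
#'
#' The elementary container of the package: one channel of a physiological
#' recording, sampled at a fixed rate, with physical units and the
#' clock time (hours, 0-24) at which the recording starts. Artifact samples
#' may be flagged through an explicit logical validity mask rather than
#' sentinel values.
#'
#' @param values numeric vector of samples in physical units.
#' @param rate sampling rate in Hz (> 0).
#' @param label channel name, e.g. `"pressure"`, `"flow"`, `"eeg"`.
#' @param units unit string, e.g. `"mmHg"`, `"mL/s"`.
#' @param start_clock clock time of the first sample, in hours of day
#'   (`0 <= start_clock < 24`). Used only for light/dark assignment.
#' @param valid optional logical vector marking valid samples; defaults to
#'   all valid. Non-finite values must be masked invalid.
#' @return an object of class `"cr_trace"`.
#' @export
trace <- function(values, rate, label = "signal", units = "",
                  start_clock = 0, valid = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("trace must contain at least one sample")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("trace rate must be a single positive number (Hz)")
  if (!is.numeric(start_clock) || start_clock < 0 || start_clock >= 24)
    stop("start_clock must lie in [0, 24)")
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  if (length(valid) != length(values))
    stop("validity mask length must match values")
  if (any(!is.finite(values) & valid))
    stop("non-finite samples must be masked invalid")
  structure(
    list(values = values, rate = rate, label = label, units = units,
         start_clock = start_clock, valid = valid),
    class = "cr_trace")
}

#' @export
print.cr_trace <- function(x, ...) {
  cat(sprintf("<cr_trace '%s'> %d samples @ %g Hz (%.1f s)%s, start %05.2fh\n",
              x$label, length(x$values), x$rate,
              trace_duration(x),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              x$start_clock))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param tr a [trace()].
#' @return numeric vector of times in seconds from recording start.
#' @export
trace_time <- function(tr) (seq_along(tr$values) - 1L) / tr$rate

#' Duration of a trace in seconds
#' @param tr a [trace()].
#' @export
trace_duration <- function(tr) length(tr$values) / tr$rate

#' Extract a time window from a trace
#'
#' Half-open window `[from_s, to_s)` in seconds from trace start.
#'
#' @param tr a [trace()].
#' @param from_s,to_s window bounds in seconds.
#' @return a new [trace()] covering the window.
#' @export
trace_window <- function(tr, from_s, to_s) {
  stopifnot(to_s > from_s)
  i0 <- max(1L, as.integer(ceiling(from_s * tr$rate + 1e-9)) + 1L)
  i1 <- min(length(tr$values), as.integer(ceiling(to_s * tr$rate - 1e-9)))
  if (i1 < i0) stop("window [", from_s, ", ", to_s, ") contains no samples")
  new_clock <- (tr$start_clock + (i0 - 1L) / tr$rate / 3600) %% 24
  trace(tr$values[i0:i1], tr$rate, tr$label, tr$units,
        start_clock = new_clock, valid = tr$valid[i0:i1])
}

#' Bundle of traces plus animal metadata
#'
#' A recording groups the channels acquired from one animal in one session
#' together with the metadata the pipelines need (group assignment, body
#' weight for ventilation normalization, lights-on hour for circadian phase
#' assignment) and optional ground-truth annotations attached by the
#' synthetic generators.
#'
#' @param animal_id identifier string.
#' @param group group label, e.g. `"control"` or `"treated"`.
#' @param body_weight_g body weight in grams (> 0).
#' @param lights_on_hour clock hour at which lights turn on (default 9,
#'   i.e. a 12h:12h cycle with lights on at 9 AM).
#' @param traces named list of [trace()] objects.
#' @param annotations optional list of ground-truth annotations.
#' @return an object of class `"cr_recording"`.
#' @export
recording <- function(animal_id, group = "control", body_weight_g = 40,
                      lights_on_hour = 9, traces = list(),
                      annotations = list()) {
  if (!is.numeric(body_weight_g) || body_weight_g <= 0)
    stop("body_weight_g must be positive")
  if (lights_on_hour < 0 || lights_on_hour >= 24)
    stop("lights_on_hour must lie in [0, 24)")
  if (length(traces) && (is.null(names(traces)) || any(!nzchar(names(traces)))))
    stop("traces must be a named list")
  structure(
    list(animal_id = as.character(animal_id), group = as.character(group),
         body_weight_g = body_weight_g, lights_on_hour = lights_on_hour,
         traces = traces, annotations = annotations),
    class = "cr_recording")
}

#' @export
print.cr_recording <- function(x, ...) {
  cat(sprintf("<cr_recording '%s'> group=%s bw=%.1fg lights_on=%gh\n",
              x$animal_id, x$group, x$body_weight_g, x$lights_on_hour))
  for (nm in names(x$traces)) {
    tr <- x$traces[[nm]]
    cat(sprintf("  %-9s %9d samples @ %6g Hz [%s]\n", nm,
                length(tr$values), tr$rate, tr$units))
  }
  if (length(x$annotations))
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}
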