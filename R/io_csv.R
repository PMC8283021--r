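#' Read a two-column CSV signal into a uniform trace
#'
#' Accepts the package's telemetry text dialect: comma-separated, UTF-8,
#' header row `time_s,value`, '.' decimal. The time column must be strictly
#' monotone increasing; the signal is resampled to the declared uniform rate
#' by linear interpolation over `[t[1], t[n]]`.
#'
#' @param path file path.
#' @param rate target uniform sampling rate in Hz.
#' @param label,units,start_clock trace metadata (see [trace()]).
#' @return a [trace()].
#' @export
read_csv_trace <- function(path, rate, label = "signal", units = "",
                           start_clock = 0) {
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("empty signal file: ", path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("expected columns 'time_s,value' in ", path)
  t <- as.numeric(df$time_s); v <- as.numeric(df$value)
  if (any(diff(t) <= 0)) stop("time column must be strictly increasing")
  if (length(t) == 1L) {
    out <- v
  } else {
    grid <- seq(t[1], t[length(t)], by = 1 / rate)
    out <- stats::approx(t, v, xout = grid, method = "linear")$y
  }
  trace(out, rate, label = label, units = units, start_clock = start_clock)
}

#' Write a trace as `time_s,value` CSV
#'
#' @param tr a [trace()].
#' @param path output file path.
#' @export
write_csv_trace <- function(tr, path) {
  utils::write.csv(
    data.frame(time_s = trace_time(tr), value = tr$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a trace by linear interpolation
#'
#' Duration is preserved to within one sample period of either rate.
#'
#' @param tr a [trace()].
#' @param new_rate target rate in Hz (> 0).
#' @return a [trace()] at `new_rate`.
#' @export
resample <- function(tr, new_rate) {
  if (!is.numeric(new_rate) || length(new_rate) != 1L || new_rate <= 0)
    stop("new_rate must be positive")
  if (abs(new_rate - tr$rate) < 1e-12) return(tr)
  t_old <- trace_time(tr)
  grid <- seq(0, t_old[length(t_old)], by = 1 / new_rate)
  v <- stats::approx(t_old, tr$values, xout = grid, method = "linear",
                     rule = 2)$y
  trace(v, new_rate, tr$label, tr$units, tr$start_clock)
}

#' Write ground-truth annotations to a JSON sidecar
#'
#' Serializes a recording's annotation list (hypnogram, event list, hourly
#' blood-pressure truth, ...) next to the signal files.
#'
#' @param annotations a list, typically `rec$annotations`.
#' @param path output `.json` path.
#' @export
write_ground_truth <- function(annotations, path) {
  jsonlite::write_json(annotations, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path path written by [write_ground_truth()].
#' @return a list.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
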