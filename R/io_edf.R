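# Minimal EDF (European Data Format) reader/writer.
#
# EDF is the community container for polysomnography: a 256-byte ASCII
# global header, 256 ASCII bytes per signal, then fixed-duration data
# records of 16-bit little-endian integers with per-signal linear
# physical scaling. This implementation covers plain continuous EDF
# (no EDF+ annotations), one record per second, which is all the
# pipelines need.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Each trace becomes one EDF signal. Record duration is 1 s, so every
#' trace rate must be a whole number of Hz; traces are truncated to the
#' common whole number of seconds. Values are linearly quantized to the
#' 16-bit digital range, so round-trip error is bounded by half a
#' quantization step (physical range / 2^16).
#'
#' @param rec a [recording()] with at least one trace.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  traces <- rec$traces
  ns <- length(traces)
  if (ns == 0L) stop("recording has no traces to write")
  rates <- vapply(traces, function(tr) tr$rate, 0)
  if (any(abs(rates - round(rates)) > 1e-9))
    stop("EDF export requires whole-number sampling rates (1-s records)")
  rates <- as.integer(round(rates))
  n_rec <- min(vapply(traces, function(tr)
    floor(length(tr$values) / tr$rate), 0))
  if (n_rec < 1L) stop("traces shorter than one 1-s record")

  pmin_ <- pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    v <- traces[[i]]$values[seq_len(n_rec * rates[i])]
    lo <- min(v); hi <- max(v)
    if (hi - lo < 1e-9) { lo <- lo - 1; hi <- hi + 1 }
    pad <- (hi - lo) * 1e-6
    pmin_[i] <- lo - pad; pmax_[i] <- hi + pad
    dig[[i]] <- as.integer(round((v - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                                   65534 - 32767))
  }

  clock <- traces[[1]]$start_clock
  hh <- floor(clock); mm <- floor((clock - hh) * 60)
  ss <- floor(((clock - hh) * 60 - mm) * 60)
  patient <- sprintf("%s group=%s bw=%g lights=%g", rec$animal_id, rec$group,
                     rec$body_weight_g, rec$lights_on_hour)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(patient, 80))
  wr(edf_pad("cardioresp synthetic recording", 80))
  wr(edf_pad("01.01.26", 8))
  wr(edf_pad(sprintf("%02d.%02d.%02d", hh, mm, ss), 8))
  wr(edf_num(256L * (ns + 1L), 8))
  wr(edf_pad("", 44))
  wr(edf_num(n_rec, 8))
  wr(edf_num(1, 8))
  wr(edf_num(ns, 4))
  lab <- names(traces)
  wr(paste0(vapply(lab, edf_pad, "", width = 16), collapse = ""))
  wr(paste0(rep(edf_pad("synthetic", 80), ns), collapse = ""))
  wr(paste0(vapply(traces, function(tr) edf_pad(tr$units, 8), ""),
            collapse = ""))
  wr(paste0(vapply(pmin_, edf_num, "", width = 8), collapse = ""))
  wr(paste0(vapply(pmax_, edf_num, "", width = 8), collapse = ""))
  wr(paste0(rep(edf_num(-32767, 8), ns), collapse = ""))
  wr(paste0(rep(edf_num(32767, 8), ns), collapse = ""))
  wr(paste0(rep(edf_pad("", 80), ns), collapse = ""))
  wr(paste0(vapply(rates, edf_num, "", width = 8), collapse = ""))
  wr(paste0(rep(edf_pad("", 32), ns), collapse = ""))

  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * rates[i] + 1L):(r * rates[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

edf_field <- function(raw, off, len) {
  trimws(rawToChar(raw[(off + 1):(off + len)]))
}

edf_numfield <- function(raw, off, len, what) {
  s <- edf_field(raw, off, len)
  x <- suppressWarnings(as.numeric(s))
  if (is.na(x)) stop("malformed EDF header field '", what, "': '", s, "'")
  x
}

#' Read an EDF file into a recording
#'
#' Parses the standard header, applies per-signal physical scaling, and
#' derives each sampling rate as samples-per-record / record duration.
#' Animal metadata written by [write_edf()] is recovered from the patient
#' identification field when present.
#'
#' @param path an EDF file.
#' @return a [recording()].
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (truncated header): ", path)
  raw <- readBin(path, "raw", n = sz)
  if (edf_field(raw, 0, 8) != "0")
    stop("malformed EDF header field 'version': expected '0'")
  patient <- edf_field(raw, 8, 80)
  start_time <- edf_field(raw, 176, 8)
  n_rec <- edf_numfield(raw, 236, 8, "number of data records")
  rec_dur <- edf_numfield(raw, 244, 8, "record duration")
  ns <- edf_numfield(raw, 252, 4, "number of signals")
  if (ns < 1) stop("malformed EDF header field 'number of signals': ", ns)
  ns <- as.integer(ns)
  if (rec_dur <= 0) stop("malformed EDF header field 'record duration'")

  off <- 256
  fld <- function(len) {
    out <- vapply(seq_len(ns), function(i)
      edf_field(raw, off + (i - 1L) * len, len), "")
    off <<- off + ns * len
    out
  }
  labels <- fld(16); fld(80)
  units <- fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  nsamp <- as.numeric(fld(8)); fld(32)
  if (any(is.na(c(pmin_, pmax_, dmin, dmax, nsamp))))
    stop("malformed EDF header field: non-numeric signal scaling entry")
  if (any(nsamp < 1)) stop("malformed EDF header field 'samples per record'")
  nsamp <- as.integer(nsamp)

  hdr_bytes <- 256L * (ns + 1L)
  per_rec <- sum(nsamp)
  data <- readBin(raw[(hdr_bytes + 1L):sz], "integer", size = 2L,
                  n = (sz - hdr_bytes) %/% 2L, endian = "little")
  n_rec <- min(n_rec, floor(length(data) / per_rec))
  if (n_rec < 1) stop("EDF file contains no complete data records")

  clock <- {
    p <- suppressWarnings(as.numeric(strsplit(start_time, ".", fixed = TRUE)[[1]]))
    if (length(p) == 3 && !any(is.na(p))) p[1] + p[2] / 60 + p[3] / 3600 else 0
  }

  # reshape record-interleaved samples into per-signal vectors
  mat_idx <- rep(rep(seq_len(ns), times = nsamp), times = n_rec)
  data <- data[seq_len(per_rec * n_rec)]
  traces <- vector("list", ns)
  for (i in seq_len(ns)) {
    d <- data[mat_idx == i]
    v <- (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) + pmin_[i]
    traces[[i]] <- trace(v, nsamp[i] / rec_dur, label = labels[i],
                         units = units[i], start_clock = clock %% 24)
  }
  names(traces) <- make.unique(labels)

  meta <- list(animal_id = sub(" .*", "", patient), group = "control",
               bw = 40, lights = 9)
  for (kv in c("group", "bw", "lights")) {
    m <- regmatches(patient, regexec(paste0(kv, "=([^ ]+)"), patient))[[1]]
    if (length(m) == 2) meta[[kv]] <- m[2]
  }
  recording(animal_id = meta$animal_id, group = meta$group,
            body_weight_g = as.numeric(meta$bw),
            lights_on_hour = as.numeric(meta$lights), traces = traces)
}
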