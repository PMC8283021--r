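# Hypoxic ventilatory response: analysis of one normoxia -> hypoxia cycle.

#' Analysis windows of a hypoxic challenge
#'
#' The normoxic reference window is the final `normoxic_ref_s` (default
#' 5 min) of the normoxic period, `[onset - normoxic_ref_s, onset)`; the
#' hypoxic window covers the early sustained response, from 30 s to 2 min
#' after the switch, `[onset + 30, onset + 120)`.
#'
#' @param rec a [recording()] of the challenge (must cover
#'   `[onset - normoxic_ref_s, onset + hypoxic_to_s]`).
#' @param hypoxia_onset_s time of the switch (defaults to the recording's
#'   annotation).
#' @param normoxic_ref_s,hypoxic_from_s,hypoxic_to_s window parameters.
#' @return list with `normoxia` and `hypoxia`, each `c(from_s, to_s)`.
#' @export
split_challenge <- function(rec, hypoxia_onset_s =
                              rec$annotations$hypoxia_onset_s,
                            normoxic_ref_s = 300, hypoxic_from_s = 30,
                            hypoxic_to_s = 120) {
  if (is.null(hypoxia_onset_s)) stop("hypoxia onset time not supplied")
  dur <- max(vapply(rec$traces, trace_duration, 0))
  if (hypoxia_onset_s - normoxic_ref_s < 0 ||
      hypoxia_onset_s + hypoxic_to_s > dur + 1e-9)
    stop("recording does not cover [onset - ", normoxic_ref_s, ", onset + ",
         hypoxic_to_s, "] s")
  list(normoxia = c(hypoxia_onset_s - normoxic_ref_s, hypoxia_onset_s),
       hypoxia = c(hypoxia_onset_s + hypoxic_from_s,
                   hypoxia_onset_s + hypoxic_to_s))
}

#' Compute the hypoxic ventilatory response
#'
#' Per-breath minute ventilation (from [segment_breaths()]) is paired with
#' the concurrent SpO2 sample (nearest-sample lookup at breath onset) in
#' both analysis windows; the HVR is the ordinary least-squares slope of
#' V_E (mL/min) on SpO2 (%) over the pooled breath-level points, sign
#' flipped and normalized by body weight so that a rise in ventilation as
#' saturation falls is reported positive. `method = "two_point"` regresses
#' the two window means instead (identical slope for two equally weighted
#' clusters).
#'
#' @param rec a [recording()] with `flow` and `spo2` traces.
#' @param windows from [split_challenge()] (computed if `NULL`).
#' @param body_weight_g body weight (defaults to the recording's).
#' @param method `"pooled"` (default) or `"two_point"`.
#' @param config a [cr_config()].
#' @return an object of class `"cr_hvr_result"`: `ve_normoxia`,
#'   `ve_hypoxia` (mL/min/g), `spo2_normoxia`, `spo2_hypoxia` (%),
#'   `slope_raw` (mL/min per %SpO2), `hvr` (mL/min/g per %SpO2),
#'   `n_breaths`.
#' @export
compute_hvr <- function(rec, windows = NULL,
                        body_weight_g = rec$body_weight_g,
                        method = c("pooled", "two_point"),
                        config = cr_config()) {
  method <- match.arg(method)
  if (is.null(rec$traces$flow) || is.null(rec$traces$spo2))
    stop("recording must contain 'flow' and 'spo2' traces")
  if (is.null(body_weight_g) || body_weight_g <= 0)
    stop("body weight must be positive")
  if (is.null(windows)) windows <- split_challenge(rec)

  flow <- rec$traces$flow
  spo2 <- rec$traces$spo2
  breaths <- segment_breaths(flow, config)
  if (nrow(breaths) == 0L) stop("no breaths detected")

  pick <- function(win) {
    b <- breaths[breaths$onset >= win[1] & breaths$onset < win[2], ]
    if (nrow(b) == 0L) stop("no breaths in window [", win[1], ", ",
                            win[2], ")")
    idx <- pmin(pmax(as.integer(round(b$onset * spo2$rate)) + 1L, 1L),
                length(spo2$values))
    data.frame(ve = b$VE_inst, spo2 = spo2$values[idx])
  }
  pn <- pick(windows$normoxia)
  ph <- pick(windows$hypoxia)

  if (method == "pooled") {
    pts <- rbind(pn, ph)
    if (stats::var(pts$spo2) <= 0) stop("degenerate regression: SpO2 variance is zero")
    slope <- stats::cov(pts$spo2, pts$ve) / stats::var(pts$spo2)
  } else {
    x <- c(mean(pn$spo2), mean(ph$spo2))
    y <- c(mean(pn$ve), mean(ph$ve))
    if (abs(x[1] - x[2]) < 1e-12) stop("degenerate regression: SpO2 variance is zero")
    slope <- diff(y) / diff(x)
  }

  structure(
    list(ve_normoxia = mean(pn$ve) / body_weight_g,
         ve_hypoxia = mean(ph$ve) / body_weight_g,
         spo2_normoxia = mean(pn$spo2), spo2_hypoxia = mean(ph$spo2),
         slope_raw = slope, hvr = -slope / body_weight_g,
         n_breaths = nrow(pn) + nrow(ph), method = method),
    class = "cr_hvr_result")
}

#' @export
print.cr_hvr_result <- function(x, ...) {
  cat(sprintf(paste0("<cr_hvr_result> VE %.3f -> %.3f mL/min/g, ",
                     "SpO2 %.1f -> %.1f %%, HVR %.4f mL/min/g/%% ",
                     "(%d breaths, %s)\n"),
              x$ve_normoxia, x$ve_hypoxia, x$spo2_normoxia, x$spo2_hypoxia,
              x$hvr, x$n_breaths, x$method))
  invisible(x)
}
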