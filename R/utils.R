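# Internal helpers shared across modules.

# Evaluate `code` with a locally seeded RNG, restoring global RNG state on exit
# so generators are deterministic without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Centered moving average with edge shrinkage; k is forced odd.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < k) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) -> y
  # fill the filter's NA edges with the original samples
  bad <- is.na(y)
  y[bad] <- x[bad]
  y
}

#' Standard error of the mean
#'
#' @param x numeric vector (NAs removed).
#' @return `sd(x)/sqrt(n)`; `NA` for fewer than two observations.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
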