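# Brute-force enumeration oracles for the exact rank tests.
mw_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  idx <- utils::combn(nx + ny, nx)
  u_all <- apply(idx, 2, function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  p <- 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9))
  list(u = u_obs, p = min(1, p))
}

wsr_oracle <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p <- 2 * min(mean(v_all <= v_obs + 1e-9), mean(v_all >= v_obs - 1e-9))
  list(w = min(v_obs, n * (n + 1) / 2 - v_obs), p = min(1, p))
}

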