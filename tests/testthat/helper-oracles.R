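# Independent oracles, deliberately written without the package's grid/root
# machinery so they can cross-check it.

# Brute-force Crooks-Bayes posterior moments: direct product of logistic
# likelihood terms on a caller-supplied dense grid, trapezoid-integrated in
# plain R.
oracle_cb_moments <- function(fwd, bwd, beta, grid) {
  M <- log(length(fwd) / length(bwd))
  ll <- vapply(grid, function(g) {
    sum(plogis(beta * (fwd - g) + M, log.p = TRUE)) +
      sum(plogis(beta * (bwd + g) - M, log.p = TRUE))
  }, 0)
  d <- exp(ll - max(ll))
  trap <- function(y) sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2)
  d <- d / trap(d)
  m <- trap(grid * d)
  list(mean = m, sd = sqrt(trap((grid - m)^2 * d)))
}

# Brute-force BAR residual scan: the root of the likelihood stationarity
# condition sum_F f(-(beta(W-g)+M)) = sum_B f(-(beta(W+g)-M)) (the CB
# posterior-mode equation; for equal counts equivalent to the familiar
# logistic balance via f(-x) = 1 - f(x)), bracketed at the given resolution.
oracle_bar_scan <- function(fwd, bwd, beta, lo, hi, resolution = 1e-4) {
  M <- log(length(fwd) / length(bwd))
  g <- seq(lo, hi, by = resolution)
  res <- vapply(g, function(gg) {
    sum(plogis(-beta * (fwd - gg) - M)) - sum(plogis(-beta * (bwd + gg) + M))
  }, 0)
  g[which.min(abs(res))]
}

tiny_workset <- function(fwd, bwd, temperature = 298) {
  workset(fwd, bwd, make_thermo(temperature), label = "tiny")
}
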