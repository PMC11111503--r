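# Closed-form results for the constant-coefficient DDM (drift mu, noise sd
# sigma, absorbing boundaries at +/-Z, start 0): absorption probability at
# the upper boundary and unconditional mean first-passage time.
ddm_accuracy_closed_form <- function(mu, sigma, Z = 1) {
  1 / (1 + exp(-2 * mu * Z / sigma^2))
}

ddm_mean_dt_closed_form <- function(mu, sigma, Z = 1) {
  (Z / mu) * tanh(mu * Z / sigma^2)
}

# Direct (unsimplified) evaluation of the logistic gain function, used as
# an independent check of the package's overflow-safe form.
gamma_direct <- function(t, d, sx, sy) {
  sy * exp(sx * (t - d)) / (1 + exp(sx * (t - d))) +
    (1 + (1 - sy) * exp(-sx * d)) / (1 + exp(-sx * d))
}

# Brute-force Kruskal-Wallis H with tie correction, written independently
# of stats::kruskal.test: rank everything, sum squared rank-sums.
kw_brute_force <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  r <- rank(x)
  sizes <- vapply(groups, length, 1L)
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  rs <- mapply(function(a, b) sum(r[a:b]), starts, ends)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction > 0) h <- h / correction
  h
}

# Per-boundary Kolmogorov-Smirnov distance between simulated RTs and a
# model RT distribution (conditional CDFs normalized per boundary).
ks_boundary <- function(trials, rt_dist, boundary_correct) {
  x <- sort(trials$rt[trials$decided & trials$correct == boundary_correct])
  dens <- if (boundary_correct) rt_dist$p_correct_rt else rt_dist$p_error_rt
  cdf <- cumsum(dens) * rt_dist$dt
  cdf <- cdf / cdf[length(cdf)]
  fm <- stats::approx(rt_dist$t, cdf, xout = x, yleft = 0, yright = 1)$y
  fe <- seq_along(x) / length(x)
  max(abs(fm - fe), abs(fm - (fe - 1 / length(x))))
}
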