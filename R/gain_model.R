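#' Logistic time-variant gain parameters
#'
#' Constructs the parameter set of the logistic gain (urgency) function
#' \eqn{\gamma(t)}: a time offset `d` (s), a slope `sx` (1/s) and an
#' amplitude scale `sy` (dimensionless). The gain is constrained to equal 1
#' at stimulus onset (`t = 0`) for every admissible parameter combination,
#' so `sy` scales the range of the gain excursion rather than its starting
#' value.
#'
#' @param d Time offset of the logistic transition, in seconds.
#' @param sx Slope of the logistic transition, in 1/s. Must be `>= 0` so the
#'   gain is non-decreasing over time (the urgency interpretation).
#' @param sy Amplitude scale (dimensionless).
#' @return An object of class `"gain_params"`.
#' @examples
#' gp <- gain_params(d = 0.5, sx = 4, sy = 3)
#' gamma_gain(0, gp) # exactly 1
#' @export
gain_params <- function(d, sx, sy) {
  vals <- c(d = d, sx = sx, sy = sy)
  if (!all(is.finite(vals))) {
    stop("gain parameters must be finite numbers", call. = FALSE)
  }
  if (sx < 0) {
    stop("`sx` must be >= 0 (non-decreasing gain)", call. = FALSE)
  }
  structure(list(d = d, sx = sx, sy = sy), class = "gain_params")
}

#' Evaluate the time-variant gain function
#'
#' Computes \eqn{\gamma(t) = s_y \sigma(s_x (t - d)) + \sigma(s_x d) +
#' (1 - s_y)\sigma(-s_x d)} where \eqn{\sigma} is the logistic sigmoid.
#' This is an overflow-safe rearrangement of the two-term logistic form:
#' \eqn{s_y e^{s_x(t-d)} / (1 + e^{s_x(t-d)}) +
#' (1 + (1 - s_y) e^{-s_x d}) / (1 + e^{-s_x d})}. The identity
#' \eqn{\gamma(0) = 1} holds exactly for all parameters, and with
#' `sx = 0` the gain is identically 1 (the constant-gain, standard-DDM
#' limit).
#'
#' @param t Time(s) since stimulus onset, in seconds; vectorized.
#' @param gp A [gain_params()] object, or a [model_spec()] whose gain is
#'   used.
#' @return Numeric vector of gain values, same length as `t`.
#' @export
gamma_gain <- function(t, gp) {
  if (inherits(gp, "ddm_spec")) gp <- gp$gain
  stopifnot(inherits(gp, "gain_params"))
  if (!all(is.finite(t))) stop("`t` must be finite", call. = FALSE)
  cpp_gamma(as.numeric(t), gp$d, gp$sx, gp$sy)
}

case_table <- function() {
  tibble::tibble(
    label = c("I", "II", "III", "IV"),
    gain_on_drift = c(TRUE, TRUE, FALSE, TRUE),
    gain_on_noise = c(TRUE, TRUE, TRUE, FALSE),
    noise_depends_on_coherence = c(TRUE, FALSE, FALSE, FALSE)
  )
}

#' Model case: where the time-variant gain applies
#'
#' The four model cases place the gain on different terms of the diffusion:
#' * **I** — gain on drift and noise, noise depends on coherence
#'   (\eqn{\sigma = \sigma_0\sqrt{1+|c|}}); the control condition.
#' * **II** — gain on drift and noise, noise independent of coherence.
#' * **III** — gain on the noise term only.
#' * **IV** — gain on the drift rate only.
#'
#' No other flag combinations are constructible.
#'
#' @param label One of `"I"`, `"II"`, `"III"`, `"IV"` (lower-case and arabic
#'   numerals `1:4` accepted).
#' @return An object of class `"ddm_case"` with fields `label`,
#'   `gain_on_drift`, `gain_on_noise`, `noise_depends_on_coherence`.
#' @export
model_case <- function(label) {
  tab <- case_table()
  if (is.numeric(label) && label %in% 1:4) label <- tab$label[label]
  label <- toupper(as.character(label))
  i <- match(label, tab$label)
  if (is.na(i)) {
    stop("unknown model case: must be one of I, II, III, IV", call. = FALSE)
  }
  structure(as.list(tab[i, ]), class = "ddm_case")
}

#' Full model specification for one case
#'
#' Bundles all parameters of one time-variant gain DDM. The decision
#' variable starts at `x0 = 0` and accumulates until it reaches an absorbing
#' threshold at `+Z` (correct, for positive drift) or `-Z` (error), with
#' `Z = 1` fixed; neither is a free parameter. The drift rate is
#' \eqn{\mu = k c} for signed coherence `c`, the baseline noise standard
#' deviation is \eqn{\sigma_0} (scaled by \eqn{\sqrt{1+|c|}} in case I),
#' and the observed RT is the decision time plus a Gaussian residual
#' (non-decision) time. The free-parameter vector has length exactly 7 for
#' every case: `(k, sigma0, d, sx, sy, t_res_mean, t_res_sd)`.
#'
#' @param case A [model_case()] or a case label.
#' @param k Drift proportionality constant (1/s per unit coherence).
#' @param sigma0 Baseline noise standard deviation (1/sqrt(s)); `> 0`.
#' @param d,sx,sy Gain parameters, see [gain_params()].
#' @param t_res_mean Mean residual (non-decision) time, in seconds; `>= 0`.
#' @param t_res_sd Residual-time standard deviation, in seconds; `>= 0`.
#' @return An object of class `"ddm_spec"`.
#' @examples
#' spec <- model_spec("IV", k = 5, sigma0 = 1, d = 0.4, sx = 5, sy = 4,
#'                    t_res_mean = 0.25, t_res_sd = 0.05)
#' drift_rate(c(0, 0.5, 1), 0.2, spec)
#' @export
model_spec <- function(case, k, sigma0, d, sx, sy, t_res_mean, t_res_sd) {
  if (!inherits(case, "ddm_case")) case <- model_case(case)
  vals <- c(k = k, sigma0 = sigma0, t_res_mean = t_res_mean,
            t_res_sd = t_res_sd)
  if (!all(is.finite(vals))) {
    stop("model parameters must be finite", call. = FALSE)
  }
  if (sigma0 <= 0) stop("`sigma0` must be > 0", call. = FALSE)
  if (t_res_mean < 0) stop("`t_res_mean` must be >= 0", call. = FALSE)
  if (t_res_sd < 0) stop("`t_res_sd` must be >= 0", call. = FALSE)
  structure(
    list(case = case, k = k, sigma0 = sigma0,
         gain = gain_params(d, sx, sy),
         t_res_mean = t_res_mean, t_res_sd = t_res_sd,
         Z = 1, x0 = 0),
    class = "ddm_spec"
  )
}

#' @export
print.ddm_spec <- function(x, ...) {
  cat(sprintf("<ddm_spec> case %s\n", x$case$label))
  cat(sprintf("  k = %.4g, sigma0 = %.4g\n", x$k, x$sigma0))
  cat(sprintf("  gain: d = %.4g s, sx = %.4g 1/s, sy = %.4g\n",
              x$gain$d, x$gain$sx, x$gain$sy))
  cat(sprintf("  residual time: mean = %.4g s, sd = %.4g s\n",
              x$t_res_mean, x$t_res_sd))
  cat(sprintf("  thresholds +/-%g, start %g (fixed)\n", x$Z, x$x0))
  invisible(x)
}

check_coherence <- function(c) {
  if (!all(is.finite(c)) || any(abs(c) > 1)) {
    stop("coherence must be finite with |c| <= 1", call. = FALSE)
  }
  c
}

#' Effective drift rate at time t
#'
#' Returns \eqn{k c \gamma(t)} when the case places gain on the drift
#' (cases I, II, IV) and the time-constant \eqn{k c} otherwise (case III).
#'
#' @param t Time(s) in seconds; vectorized.
#' @param c Signed coherence in \[-1, 1\].
#' @param spec A [model_spec()].
#' @return Drift rate (1/s), same length as `t`.
#' @export
drift_rate <- function(t, c, spec) {
  stopifnot(inherits(spec, "ddm_spec"))
  check_coherence(c)
  mu0 <- spec$k * c
  if (spec$case$gain_on_drift) mu0 * gamma_gain(t, spec$gain)
  else rep(mu0, length(t))
}

#' Effective noise standard deviation at time t
#'
#' The baseline is \eqn{\sigma_0\sqrt{1+|c|}} when the case's noise depends
#' on coherence (case I; variance doubles for a fully coherent stimulus)
#' and \eqn{\sigma_0} otherwise. The gain multiplies this baseline in cases
#' I-III; in case IV the noise is time-constant.
#'
#' @inheritParams drift_rate
#' @return Noise standard deviation (1/sqrt(s)), strictly positive.
#' @export
noise_sd <- function(t, c, spec) {
  stopifnot(inherits(spec, "ddm_spec"))
  check_coherence(c)
  base <- if (spec$case$noise_depends_on_coherence) {
    spec$sigma0 * sqrt(1 + abs(c))
  } else {
    spec$sigma0
  }
  if (spec$case$gain_on_noise) base * gamma_gain(t, spec$gain)
  else rep(base, length(t))
}

param_names <- function() {
  c("k", "sigma0", "d", "sx", "sy", "t_res_mean", "t_res_sd")
}

#' Free-parameter vector of a model specification
#'
#' Every case has the same seven free parameters
#' `(k, sigma0, d, sx, sy, t_res_mean, t_res_sd)`; the threshold and
#' starting point are fixed.
#'
#' @param spec A [model_spec()].
#' @return Named numeric vector of length 7.
#' @export
free_params <- function(spec) {
  stopifnot(inherits(spec, "ddm_spec"))
  setNames(
    c(spec$k, spec$sigma0, spec$gain$d, spec$gain$sx, spec$gain$sy,
      spec$t_res_mean, spec$t_res_sd),
    param_names()
  )
}

#' Build a model specification from a free-parameter vector
#'
#' @param par Numeric vector of length 7 in the order
#'   `(k, sigma0, d, sx, sy, t_res_mean, t_res_sd)`.
#' @param case A [model_case()] or case label.
#' @return A [model_spec()].
#' @export
spec_from_params <- function(par, case) {
  stopifnot(length(par) == 7)
  model_spec(case, k = par[[1]], sigma0 = par[[2]], d = par[[3]],
             sx = par[[4]], sy = par[[5]], t_res_mean = par[[6]],
             t_res_sd = par[[7]])
}

#' Default fitting bounds for the seven free parameters
#'
#' Box bounds used by [fit_case()]: `k` in \[0, 50\], `sigma0` in
#' \[0.01, 5\], `d` in \[0, 5\] s, `sx` in \[0, 20\] 1/s, `sy` in \[0, 20\],
#' `t_res_mean` in \[0, 1\] s, `t_res_sd` in \[0, 0.5\] s. These bracket all
#' gain shapes the package's presets produce; they are a package choice,
#' not an estimate.
#'
#' @return A list with named numeric vectors `lower` and `upper`, each of
#'   length 7.
#' @export
default_bounds <- function() {
  list(
    lower = setNames(c(0, 0.01, 0, 0, 0, 0, 0), param_names()),
    upper = setNames(c(50, 5, 5, 20, 20, 1, 0.5), param_names())
  )
}

#' Serialize a model specification to JSON
#'
#' Writes the keys `case, k, sigma0, d, sx, sy, t_res_mean, t_res_sd`;
#' the round trip through [spec_from_json()] is lossless.
#'
#' @param spec A [model_spec()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "ddm_spec"))
  doc <- list(case = spec$case$label, k = spec$k, sigma0 = spec$sigma0,
              d = spec$gain$d, sx = spec$gain$sx, sy = spec$gain$sy,
              t_res_mean = spec$t_res_mean, t_res_sd = spec$t_res_sd)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a model specification from JSON
#'
#' @param x A JSON string or a path to a JSON file produced by
#'   [spec_to_json()].
#' @return A [model_spec()].
#' @export
spec_from_json <- function(x) {
  if (length(x) == 1 && !grepl("\\{", x) && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(x)
  model_spec(doc$case, k = doc$k, sigma0 = doc$sigma0, d = doc$d,
             sx = doc$sx, sy = doc$sy, t_res_mean = doc$t_res_mean,
             t_res_sd = doc$t_res_sd)
}
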