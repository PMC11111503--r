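#' Monte-Carlo simulation of single trials
#'
#' Euler-Maruyama integration of the time-variant gain diffusion: the
#' decision variable starts at 0 and accumulates increments
#' `drift * dt + sqrt(dt) * noise_sd * eta` (eta standard normal, with
#' drift and noise frozen at each step's midpoint time, matching the
#' solver) until it crosses +/-1 or the horizon `t_max` is reached. A trial
#' terminates at the first grid time with `|X| >= 1` (no interpolation).
#' Decided trials receive a Gaussian residual time (mean `t_res_mean`, sd
#' `t_res_sd`, truncated at 0 by rejection) added to the decision time.
#' The same `seed` reproduces the identical trial table.
#'
#' @param spec A [model_spec()].
#' @param c Coherence (motion strength), `|c| <= 1`.
#' @param n Number of trials, `>= 1`.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @param grid A [solver_grid()] supplying `dt` and `t_max`.
#' @return A [tibble::tibble()] with one row per trial: `coherence`,
#'   `correct` (upper boundary hit), `rt` (s; `NA` when undecided),
#'   `decided`.
#' @examples
#' spec <- case_preset("IV")
#' trials <- simulate_trials(spec, c = 0.2, n = 500, seed = 1)
#' mean(trials$correct[trials$decided])
#' @export
simulate_trials <- function(spec, c, n, seed = NULL, grid = solver_grid()) {
  stopifnot(inherits(spec, "ddm_spec"), inherits(grid, "solver_grid"))
  check_coherence(c)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cs <- spec$case
  out <- cpp_simulate(spec$k, spec$sigma0, spec$gain$d, spec$gain$sx,
                      spec$gain$sy, cs$gain_on_drift, cs$gain_on_noise,
                      cs$noise_depends_on_coherence, c, as.integer(n),
                      grid$dt, grid$t_max, spec$t_res_mean, spec$t_res_sd)
  tibble::tibble(
    coherence = rep(c, n),
    correct = out$correct,
    rt = out$rt,
    decided = out$decided
  )
}
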