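#' Space-time discretization for the Fokker-Planck solver
#'
#' Defaults follow the package's fitting convention: trial horizon
#' `t_max = 5` s with time step `dt = 0.01` s, and `nx = 201` interior
#' spatial points between the absorbing boundaries at -1 and +1 (so the
#' spatial step divides the threshold separation evenly and the starting
#' point x = 0 lies on the grid).
#'
#' @param dt Time step in seconds; `t_max / dt` must be integral.
#' @param t_max Trial horizon in seconds.
#' @param nx Number of interior spatial points; odd, `>= 3`.
#' @return An object of class `"solver_grid"`.
#' @export
solver_grid <- function(dt = 0.01, t_max = 5, nx = 201) {
  if (dt <= 0 || t_max <= 0) stop("`dt` and `t_max` must be > 0", call. = FALSE)
  nt <- t_max / dt
  if (abs(nt - round(nt)) > 1e-8) {
    stop("`t_max / dt` must be an integer number of steps", call. = FALSE)
  }
  if (nx < 3 || nx %% 2 == 0) {
    stop("`nx` must be odd and >= 3 so that x = 0 is a grid point",
         call. = FALSE)
  }
  structure(list(dt = dt, t_max = t_max, nx = as.integer(nx),
                 nt = as.integer(round(nt))),
            class = "solver_grid")
}

#' First-passage-time densities for one coherence
#'
#' Forward-solves the Fokker-Planck equation of the time-variant gain
#' diffusion — drift \eqn{\mu(t)} from [drift_rate()], diffusion
#' \eqn{\sigma(t)^2/2} from [noise_sd()] — with a delta initial condition
#' at 0 and absorbing boundaries at +/-1. Space is discretized with
#' Scharfetter-Gummel (exponential-fitting) weights, which reduce to
#' central differencing at small cell Peclet number and to upwinding at
#' large; time stepping is Crank-Nicolson with coefficients frozen at each
#' step's midpoint, falling back to backward Euler for the first two steps
#' (Rannacher start-up for the delta initial condition) and in strongly
#' advective regimes. The boundary fluxes are the first-passage-time
#' densities of the upper (correct) and lower (error) boundary; the
#' interior mass left at `t_max` is reported as survival (undecided)
#' probability and treated as censored downstream.
#'
#' @param spec A [model_spec()].
#' @param c Coherence (motion strength); fitted models use `|c|` with
#'   correct responses mapped to the upper boundary.
#' @param grid A [solver_grid()].
#' @return An object of class `"fptd"`: list with `t` (midpoint time grid,
#'   s), `f_upper` and `f_lower` (densities, 1/s), `survival`
#'   (probability), plus the grid and coherence. Satisfies
#'   `dt * sum(f_upper + f_lower) + survival = 1` up to the scheme's
#'   conservation error (< 1e-3 on the shipped presets).
#' @export
solve_fptd <- function(spec, c, grid = solver_grid()) {
  stopifnot(inherits(spec, "ddm_spec"), inherits(grid, "solver_grid"))
  check_coherence(c)
  cs <- spec$case
  out <- cpp_solve_fptd(spec$k, spec$sigma0, spec$gain$d, spec$gain$sx,
                        spec$gain$sy, cs$gain_on_drift, cs$gain_on_noise,
                        cs$noise_depends_on_coherence, c,
                        grid$dt, grid$t_max, grid$nx)
  structure(list(t = out$t, f_upper = out$f_upper, f_lower = out$f_lower,
                 survival = out$survival, dt = grid$dt, coherence = c,
                 grid = grid),
            class = "fptd")
}

#' Convolve boundary densities with the residual-time distribution
#'
#' Each boundary's first-passage-time density is convolved with the
#' Gaussian residual (non-decision) time kernel (mean `t_res_mean`, sd
#' `t_res_sd`), discretized by bin integration on the solver time grid,
#' truncated below t = 0 and renormalized so that each boundary keeps its
#' absorbed mass. With `t_res_sd = 0` the convolution is a pure shift by
#' `t_res_mean`.
#'
#' @param fptd An [solve_fptd()] result.
#' @param spec The [model_spec()] supplying the residual-time parameters.
#' @return An object of class `"rt_dist"`: list with `t`, `p_correct_rt`,
#'   `p_error_rt` (RT densities, 1/s), `survival`, `dt`, `coherence`.
#' @export
convolve_residual <- function(fptd, spec) {
  stopifnot(inherits(fptd, "fptd"), inherits(spec, "ddm_spec"))
  pu <- cpp_convolve_residual(fptd$f_upper, fptd$dt, spec$t_res_mean,
                              spec$t_res_sd)
  pl <- cpp_convolve_residual(fptd$f_lower, fptd$dt, spec$t_res_mean,
                              spec$t_res_sd)
  structure(list(t = fptd$t, p_correct_rt = pu, p_error_rt = pl,
                 survival = fptd$survival, dt = fptd$dt,
                 coherence = fptd$coherence),
            class = "rt_dist")
}

#' Summary statistics of a predicted RT distribution
#'
#' Accuracy is the upper-boundary mass divided by the total absorbed mass
#' (undecided mass at the horizon is excluded, i.e. treated as censored).
#' Mean RTs are density-weighted averages per boundary; a boundary with
#' zero mass yields `NA` for its mean (flagged, not propagated as NaN).
#'
#' @param rt An [convolve_residual()] result.
#' @return A one-row [tibble::tibble()] with columns `accuracy`,
#'   `mean_rt_correct`, `mean_rt_error`, `mass_correct`, `mass_error`,
#'   `survival`.
#' @export
summarize_rt <- function(rt) {
  stopifnot(inherits(rt, "rt_dist"))
  mu_mass <- sum(rt$p_correct_rt) * rt$dt
  ml_mass <- sum(rt$p_error_rt) * rt$dt
  if (mu_mass <= 0 && ml_mass <= 0) {
    stop("degenerate model: no absorbed mass at either boundary",
         call. = FALSE)
  }
  mean_u <- if (mu_mass > 0) sum(rt$t * rt$p_correct_rt) * rt$dt / mu_mass else NA_real_
  mean_l <- if (ml_mass > 0) sum(rt$t * rt$p_error_rt) * rt$dt / ml_mass else NA_real_
  tibble::tibble(
    accuracy = mu_mass / (mu_mass + ml_mass),
    mean_rt_correct = mean_u,
    mean_rt_error = mean_l,
    mass_correct = mu_mass,
    mass_error = ml_mass,
    survival = rt$survival
  )
}

#' Model-predicted summaries over a coherence grid
#'
#' Convenience wrapper: solve, convolve and summarize for each coherence.
#'
#' @param spec A [model_spec()].
#' @param coherences Numeric vector of coherences.
#' @param grid A [solver_grid()].
#' @return A tibble with one row per coherence (column `coherence` plus the
#'   [summarize_rt()] columns).
#' @export
predict_summaries <- function(spec, coherences, grid = solver_grid()) {
  rows <- lapply(coherences, function(cc) {
    s <- summarize_rt(convolve_residual(solve_fptd(spec, cc, grid), spec))
    tibble::add_column(s, coherence = cc, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Export summary records to JSON
#'
#' Writes the output of [summarize_rt()], [predict_summaries()] or
#' [data_summaries()] as an array of JSON records.
#'
#' @param summaries A data frame of summary statistics.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  stopifnot(is.data.frame(summaries))
  jsonlite::write_json(summaries, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export an RT distribution to CSV
#'
#' Columns `t`, `p_correct_rt`, `p_error_rt`.
#'
#' @param rt An [convolve_residual()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rt_dist <- function(rt, path) {
  stopifnot(inherits(rt, "rt_dist"))
  utils::write.csv(
    data.frame(t = rt$t, p_correct_rt = rt$p_correct_rt,
               p_error_rt = rt$p_error_rt),
    path, row.names = FALSE
  )
  invisible(path)
}
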