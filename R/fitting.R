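trial_arrays <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0,
            all(c("coherence", "correct", "rt") %in% names(trials)))
  if ("decided" %in% names(trials)) trials <- trials[trials$decided, ]
  if (nrow(trials) == 0) stop("no decided trials", call. = FALSE)
  bad <- which(!is.finite(trials$rt) | trials$rt <= 0)
  if (length(bad) > 0) {
    stop("invalid RTs at rows: ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  coh <- sort(unique(abs(trials$coherence)))
  list(
    coh = coh,
    coh_idx = match(abs(trials$coherence), coh) - 1L,
    correct = as.logical(trials$correct),
    rt = as.numeric(trials$rt)
  )
}

#' Robust negative log likelihood of a trial table
#'
#' For each decided trial the likelihood is the model RT density at the
#' trial's (choice, RT), evaluated for that trial's coherence by linear
#' interpolation on the solver time grid and floored at `eps` (the
#' robustness guard against zero-density outliers). Returns the summed
#' negative log likelihood in nats; additive over disjoint trial subsets.
#' Undecided mass at the horizon is treated as censored and does not enter
#' the normalization.
#'
#' @param spec A [model_spec()].
#' @param trials Trial table with columns `coherence`, `correct`, `rt`
#'   (and optionally `decided`; undecided trials are excluded).
#' @param grid A [solver_grid()].
#' @param eps Likelihood floor; default `1e-10`.
#' @return The negative log likelihood (nats).
#' @export
negloglik_robust <- function(spec, trials, grid = solver_grid(), eps = 1e-10) {
  stopifnot(inherits(spec, "ddm_spec"))
  ta <- trial_arrays(trials)
  if (any(ta$rt > grid$t_max)) {
    stop("RTs beyond the solver horizon `t_max`; filter first", call. = FALSE)
  }
  cs <- spec$case
  cpp_negloglik(unname(free_params(spec)),
                c(cs$gain_on_drift, cs$gain_on_noise,
                  cs$noise_depends_on_coherence),
                ta$coh, ta$coh_idx, ta$correct, ta$rt,
                grid$dt, grid$t_max, grid$nx, eps)
}

#' Akaike information criterion from a negative log likelihood
#'
#' All four model cases have seven free parameters, so
#' `AIC = 14 - 2 * logLik = 14 + 2 * NLL`.
#'
#' @param neg_log_lik Negative log likelihood in nats.
#' @param n_params Number of free parameters (default 7).
#' @return The AIC value.
#' @export
aic_from_nll <- function(neg_log_lik, n_params = 7) {
  stopifnot(is.finite(neg_log_lik))
  2 * n_params + 2 * neg_log_lik
}

#' Per-coherence summary statistics of a trial table
#'
#' Accuracy, mean correct RT and mean error RT per coherence level,
#' computed over decided trials. Boundaries without trials yield `NA`
#' means.
#'
#' @param trials Trial table.
#' @return A tibble with columns `coherence`, `accuracy`,
#'   `mean_rt_correct`, `mean_rt_error`, `n`.
#' @export
data_summaries <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  if ("decided" %in% names(trials)) trials <- trials[trials$decided, ]
  trials$coherence <- abs(trials$coherence)
  trials |>
    dplyr::group_by(coherence = .data$coherence) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      mean_rt_correct = if (any(.data$correct)) mean(.data$rt[.data$correct]) else NA_real_,
      mean_rt_error = if (any(!.data$correct)) mean(.data$rt[!.data$correct]) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}

sq_error_between <- function(model_sum, data_sum) {
  m <- dplyr::inner_join(model_sum, data_sum, by = "coherence",
                         suffix = c("_model", "_data"))
  term <- function(a, b) ifelse(is.na(a) | is.na(b), 0, (a - b)^2)
  sum(term(m$mean_rt_correct_model, m$mean_rt_correct_data) +
        term(m$mean_rt_error_model, m$mean_rt_error_data) +
        term(m$accuracy_model, m$accuracy_data))
}

#' Summary-statistic squared error of a model against data
#'
#' Sum over coherence levels of the squared differences in mean correct
#' RT, mean error RT and accuracy between the model prediction and the
#' data; terms whose data summary is undefined (no trials of that outcome
#' at that coherence) are skipped. This is the quantity used for best-run
#' selection and case ranking.
#'
#' @inheritParams negloglik_robust
#' @return A non-negative scalar.
#' @export
squared_error <- function(spec, trials, grid = solver_grid()) {
  stopifnot(inherits(spec, "ddm_spec"))
  ds <- data_summaries(trials)
  ms <- predict_summaries(spec, ds$coherence, grid)
  sq_error_between(ms, ds)
}

#' Control settings for the differential evolution optimizer
#'
#' Defaults: population `15 * 7 = 105`, up to 500 generations, mutation
#' factor `F = 0.8`, crossover `CR = 0.9`, and a stopping tolerance of
#' `1e-6` on the population cost spread. Reduce `np`/`maxiter` for quick
#' exploratory fits.
#'
#' @param np Population size.
#' @param maxiter Maximum generations.
#' @param F Differential weight.
#' @param CR Crossover probability.
#' @param tol Stop when `max(cost) - min(cost) < tol * (|min(cost)| + tol)`.
#' @return A list of class `"de_control"`.
#' @export
de_control <- function(np = 105, maxiter = 500, F = 0.8, CR = 0.9,
                       tol = 1e-6) {
  structure(list(np = as.integer(np), maxiter = as.integer(maxiter),
                 F = F, CR = CR, tol = tol),
            class = "de_control")
}

# Plain rand/1/bin differential evolution on a box; minimizes fn.
de_optimize <- function(fn, lower, upper, control = de_control()) {
  dim <- length(lower)
  np <- max(control$np, 4L)
  pop <- matrix(runif(np * dim, lower, upper), nrow = np, ncol = dim,
                byrow = TRUE)
  cost <- apply(pop, 1, fn)
  iter <- 0L
  converged <- FALSE
  while (iter < control$maxiter) {
    iter <- iter + 1L
    for (i in seq_len(np)) {
      idx <- sample(seq_len(np)[-i], 3)
      mutant <- pop[idx[1], ] + control$F * (pop[idx[2], ] - pop[idx[3], ])
      mutant <- pmin(pmax(mutant, lower), upper)
      cross <- runif(dim) < control$CR
      cross[sample.int(dim, 1)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      f <- fn(trial)
      if (f <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- f
      }
    }
    if (max(cost) - min(cost) < control$tol * (abs(min(cost)) + control$tol)) {
      converged <- TRUE
      break
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best], iter = iter,
       converged = converged)
}

#' Fit one model case to a trial table with the multi-run protocol
#'
#' Runs a stochastic global optimizer (differential evolution) `n_runs`
#' times with distinct derived seeds, each run minimizing the robust
#' negative log likelihood [negloglik_robust()] over the seven free
#' parameters within `bounds`. Each run records its NLL, AIC
#' (`14 + 2 * NLL`) and summary-statistic [squared_error()]; the selected
#' best run is the one with the smallest squared error (ties broken by
#' lower NLL).
#'
#' @param trials Trial table (pooled group-level data).
#' @param case A [model_case()] or case label.
#' @param n_runs Number of independent optimization runs (default 18).
#' @param seed Base integer seed; run `i` uses `seed + 7919 * i`.
#' @param grid A [solver_grid()].
#' @param bounds A list with `lower`/`upper` as from [default_bounds()].
#' @param control A [de_control()].
#' @param polish Refine each run's differential-evolution solution with
#'   bounded L-BFGS-B (default `TRUE`). The global search stays stochastic
#'   per run; the polish only descends within the basin the run found.
#' @param eps Likelihood floor passed to the objective.
#' @return An object of class `"ddm_fits"`: list with `case`, `runs` (a
#'   tibble: `run`, `seed`, `neg_log_lik`, `aic`, `sq_error`, `converged`,
#'   and the seven parameters), `specs` (fitted [model_spec()] per run),
#'   `best` (index of the selected run), `best_spec`.
#' @export
fit_case <- function(trials, case, n_runs = 18, seed = 1,
                     grid = solver_grid(), bounds = default_bounds(),
                     control = de_control(), polish = TRUE, eps = 1e-10) {
  if (!inherits(case, "ddm_case")) case <- model_case(case)
  ta <- trial_arrays(trials)
  flags <- c(case$gain_on_drift, case$gain_on_noise,
             case$noise_depends_on_coherence)
  obj <- function(par) {
    cpp_negloglik(par, flags, ta$coh, ta$coh_idx, ta$correct, ta$rt,
                  grid$dt, grid$t_max, grid$nx, eps)
  }
  runs <- vector("list", n_runs)
  specs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    run_seed <- as.integer((seed + 7919 * i) %% .Machine$integer.max)
    set.seed(run_seed)
    res <- de_optimize(obj, bounds$lower, bounds$upper, control)
    if (polish) {
      pol <- stats::optim(res$par, obj, method = "L-BFGS-B",
                          lower = bounds$lower, upper = bounds$upper,
                          control = list(maxit = 200))
      if (pol$value <= res$value) {
        res$par <- pol$par
        res$value <- pol$value
      }
    }
    spec_i <- spec_from_params(res$par, case)
    specs[[i]] <- spec_i
    runs[[i]] <- tibble::tibble(
      run = i, seed = run_seed,
      neg_log_lik = res$value,
      aic = aic_from_nll(res$value),
      sq_error = squared_error(spec_i, trials, grid),
      converged = res$converged,
      !!!setNames(as.list(res$par), param_names())
    )
  }
  runs <- dplyr::bind_rows(runs)
  ord <- order(runs$sq_error, runs$neg_log_lik)
  best <- ord[1]
  structure(list(case = case, runs = runs, specs = specs, best = best,
                 best_spec = specs[[best]]),
            class = "ddm_fits")
}

#' @export
print.ddm_fits <- function(x, ...) {
  cat(sprintf("<ddm_fits> case %s, %d runs\n", x$case$label, nrow(x$runs)))
  cat(sprintf("  best run %d: NLL = %.2f, AIC = %.2f, sq. error = %.4g\n",
              x$best, x$runs$neg_log_lik[x$best], x$runs$aic[x$best],
              x$runs$sq_error[x$best]))
  invisible(x)
}

#' Serialize fit results
#'
#' Writes the per-run table as JSON (with the case label) or flat CSV
#' (one row per run).
#'
#' @param fits A [fit_case()] result.
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  stopifnot(inherits(fits, "ddm_fits"))
  if (grepl("\\.json$", path)) {
    doc <- list(case = fits$case$label, best = fits$best,
                runs = fits$runs)
    jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    df <- cbind(case = fits$case$label, fits$runs)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read fit results written by [write_fits()] (JSON form)
#'
#' @param path Path to a `.json` file from [write_fits()].
#' @return A `"ddm_fits"` object (specs rebuilt from the run table).
#' @export
read_fits <- function(path) {
  doc <- jsonlite::fromJSON(path)
  runs <- tibble::as_tibble(doc$runs)
  case <- model_case(doc$case)
  specs <- lapply(seq_len(nrow(runs)), function(i) {
    spec_from_params(unlist(runs[i, param_names()]), case)
  })
  structure(list(case = case, runs = runs, specs = specs, best = doc$best,
                 best_spec = specs[[doc$best]]),
            class = "ddm_fits")
}
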