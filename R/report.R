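save_panel <- function(plot, numbers, name, out_dir) {
  csv <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(numbers), csv, row.names = FALSE)
  png <- file.path(out_dir, paste0(name, ".png"))
  ggplot2::ggsave(png, plot, width = 7, height = 5, dpi = 120)
  c(csv = csv, png = png)
}

#' Diagnostic report for fitted model cases
#'
#' Writes, for a trial table and one or more fitted cases, the standard
#' panels: chronometric curves (mean correct/error RT vs coherence, model
#' vs data), psychometric curves (accuracy vs coherence), RT probability
#' densities at selected coherences, gain-function timecourses (all equal
#' 1 at t = 0), squared-error and AIC summaries over runs, and the
#' normalized-parameter chart when several cases are supplied. Every
#' figure is saved as PNG alongside a CSV twin holding exactly the
#' numbers plotted; the summary CSVs reproduce [predict_summaries()] /
#' [data_summaries()] output.
#'
#' @param trials Trial table (the data panel of each figure).
#' @param fits A named list (case label -> [fit_case()] result) or a
#'   single result.
#' @param out_dir Output directory, created if needed.
#' @param pdf_coherences Coherences at which to plot RT densities;
#'   defaults to the lowest and highest coherence in the data.
#' @param grid A [solver_grid()].
#' @return Named character vector of the files written, invisibly.
#' @export
report_fits <- function(trials, fits, out_dir,
                        pdf_coherences = NULL, grid = solver_grid()) {
  if (inherits(fits, "ddm_fits")) {
    fits <- setNames(list(fits), fits$case$label)
  }
  stopifnot(length(fits) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  ds <- data_summaries(trials)
  model_sum <- dplyr::bind_rows(lapply(names(fits), function(lb) {
    tibble::add_column(
      predict_summaries(fits[[lb]]$best_spec, ds$coherence, grid),
      case = lb, .before = 1)
  }))
  if (is.null(pdf_coherences)) {
    pdf_coherences <- range(ds$coherence)
  }

  # chronometric: mean RTs vs coherence, model lines over data points
  chron_model <- tidyr_longer_rt(model_sum)
  chron_data <- tidyr_longer_rt(tibble::add_column(ds, case = "data",
                                                   .before = 1))
  p <- ggplot2::ggplot(chron_model,
                       ggplot2::aes(.data$coherence, .data$mean_rt,
                                    colour = .data$case,
                                    linetype = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = chron_data,
                        ggplot2::aes(shape = .data$outcome),
                        colour = "black") +
    ggplot2::labs(x = "coherence", y = "mean RT (s)",
                  title = "Chronometric functions") +
    ggplot2::theme_minimal()
  files <- c(files, save_panel(p, dplyr::bind_rows(chron_model, chron_data),
                               "chronometric", out_dir))

  # psychometric: accuracy vs coherence
  psy <- dplyr::bind_rows(
    model_sum[, c("case", "coherence", "accuracy")],
    tibble::tibble(case = "data", coherence = ds$coherence,
                   accuracy = ds$accuracy)
  )
  p <- ggplot2::ggplot(psy[psy$case != "data", ],
                       ggplot2::aes(.data$coherence, .data$accuracy,
                                    colour = .data$case)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = psy[psy$case == "data", ], colour = "black") +
    ggplot2::labs(x = "coherence", y = "accuracy",
                  title = "Psychometric functions") +
    ggplot2::theme_minimal()
  files <- c(files, save_panel(p, psy, "psychometric", out_dir))

  # RT probability densities at the selected coherences
  dens <- dplyr::bind_rows(lapply(names(fits), function(lb) {
    dplyr::bind_rows(lapply(pdf_coherences, function(cc) {
      rt <- convolve_residual(solve_fptd(fits[[lb]]$best_spec, cc, grid),
                              fits[[lb]]$best_spec)
      tibble::tibble(case = lb, coherence = cc, t = rt$t,
                     p_correct_rt = rt$p_correct_rt,
                     p_error_rt = rt$p_error_rt)
    }))
  }))
  dens_long <- dplyr::bind_rows(
    tibble::tibble(case = dens$case, coherence = dens$coherence, t = dens$t,
                   outcome = "correct", density = dens$p_correct_rt),
    tibble::tibble(case = dens$case, coherence = dens$coherence, t = dens$t,
                   outcome = "error", density = dens$p_error_rt)
  )
  p <- ggplot2::ggplot(dens_long,
                       ggplot2::aes(.data$t, .data$density,
                                    colour = .data$case,
                                    linetype = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~coherence, scales = "free_y") +
    ggplot2::labs(x = "RT (s)", y = "density (1/s)",
                  title = "Model RT probability densities") +
    ggplot2::theme_minimal()
  files <- c(files, save_panel(p, dens, "rt_pdfs", out_dir))

  # gain timecourses (gamma(0) = 1 for every case)
  tgrid <- seq(0, grid$t_max, by = grid$dt)
  gains <- dplyr::bind_rows(lapply(names(fits), function(lb) {
    tibble::tibble(case = lb, t = tgrid,
                   gamma = gamma_gain(tgrid, fits[[lb]]$best_spec))
  }))
  p <- ggplot2::ggplot(gains, ggplot2::aes(.data$t, .data$gamma,
                                           colour = .data$case)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(gamma(t)),
                  title = "Fitted time-variant gain") +
    ggplot2::theme_minimal()
  files <- c(files, save_panel(p, gains, "gain_timecourse", out_dir))

  # squared error / AIC over runs
  runstats <- dplyr::bind_rows(lapply(names(fits), function(lb) {
    tibble::tibble(case = lb, run = fits[[lb]]$runs$run,
                   sq_error = fits[[lb]]$runs$sq_error,
                   aic = fits[[lb]]$runs$aic)
  }))
  p <- ggplot2::ggplot(runstats, ggplot2::aes(.data$case, .data$sq_error)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "case", y = "squared error",
                  title = "Model squared error over runs") +
    ggplot2::theme_minimal()
  files <- c(files, save_panel(p, runstats, "run_statistics", out_dir))

  # normalized parameters (needs >= 2 cases)
  if (length(fits) >= 2) {
    np <- normalize_params(lapply(fits, function(f) f$best_spec))
    npl <- tibble::tibble(
      case = rep(rownames(np), ncol(np)),
      parameter = rep(colnames(np), each = nrow(np)),
      value = as.vector(np)
    )
    p <- ggplot2::ggplot(npl, ggplot2::aes(.data$parameter, .data$value,
                                           fill = .data$case)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "parameter", y = "normalized value",
                    title = "Normalized model parameters") +
      ggplot2::theme_minimal()
    files <- c(files, save_panel(p, npl, "normalized_params", out_dir))
  }

  invisible(files)
}

# long format for chronometric panels; NA means dropped (e.g. no error
# trials at a coherence) so panels degrade gracefully rather than erroring
tidyr_longer_rt <- function(s) {
  out <- dplyr::bind_rows(
    tibble::tibble(case = s$case, coherence = s$coherence,
                   outcome = "correct", mean_rt = s$mean_rt_correct),
    tibble::tibble(case = s$case, coherence = s$coherence,
                   outcome = "error", mean_rt = s$mean_rt_error)
  )
  out[!is.na(out$mean_rt), ]
}
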