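#' Shipped demonstration specification for each model case
#'
#' Four specifications sharing the same drift constant, noise level, gain
#' shape and residual-time parameters, differing only in where the gain
#' applies. They illustrate the qualitative dissociation: a rising gain on
#' the noise term only (case III) makes late — hence slow — decisions more
#' error-prone (mean error RT > mean correct RT), while a rising gain on
#' the drift rate only (case IV) makes late decisions more correct (mean
#' error RT < mean correct RT).
#'
#' @param label Case label, see [model_case()].
#' @return A [model_spec()].
#' @export
case_preset <- function(label) {
  model_spec(label, k = 8, sigma0 = 1, d = 0.5, sx = 4, sy = 3,
             t_res_mean = 0.3, t_res_sd = 0.05)
}

#' Species-like synthetic dataset presets
#'
#' Each preset bundles a coherence grid, per-coherence trial counts, a
#' generating [model_spec()] with known ground truth, and the RT analysis
#' window. The presets emulate the qualitative error-vs-correct RT
#' signatures of the three species in the random-dot motion
#' discrimination task family:
#' * `rat_like` — case IV (gain on drift only): mean error RT faster than
#'   correct RT; coherences 10-50%; window (0.1, 2.5) s.
#' * `monkey_like` — case II (gain on drift and noise): mean error RT
#'   slower than correct RT; standard 0-51.2% grid; window (0.1, 1.65) s.
#' * `human_like` — near-unit gain (small amplitude, so the gain stays
#'   close to 1 over the trial): error and correct mean RTs nearly equal;
#'   coherences 2-50%; window (0.1, 2.5) s.
#'
#' The ground-truth parameter values are package choices committed as
#' fixtures (real fitted values are not published as numbers); they were
#' selected so the presets satisfy the orderings above.
#'
#' @param label One of `"rat_like"`, `"monkey_like"`, `"human_like"`.
#' @param n_per_coherence Trials simulated per coherence level (default
#'   2000, sized for smooth RT densities).
#' @return An object of class `"species_preset"`: list with `label`,
#'   `coherences`, `n_per_coherence`, `spec`, `window` (c(lo, hi) in s).
#' @examples
#' p <- species_preset("rat_like")
#' p$window
#' @export
species_preset <- function(label, n_per_coherence = 2000) {
  presets <- list(
    monkey_like = list(
      coherences = c(0, 0.032, 0.064, 0.128, 0.256, 0.512),
      spec = model_spec("II", k = 10, sigma0 = 1, d = 0.35, sx = 6, sy = 3,
                        t_res_mean = 0.3, t_res_sd = 0.05),
      window = c(0.1, 1.65),
      pdf_coherences = c(0.032, 0.128)
    ),
    human_like = list(
      coherences = c(0.02, 0.04, 0.08, 0.12, 0.25, 0.50),
      spec = model_spec("II", k = 7, sigma0 = 1, d = 0.5, sx = 2, sy = 0.1,
                        t_res_mean = 0.35, t_res_sd = 0.07),
      window = c(0.1, 2.5),
      pdf_coherences = c(0.02, 0.12)
    ),
    rat_like = list(
      coherences = c(0.10, 0.20, 0.30, 0.40, 0.50),
      spec = model_spec("IV", k = 3.5, sigma0 = 1, d = 0.4, sx = 5, sy = 4,
                        t_res_mean = 0.25, t_res_sd = 0.05),
      window = c(0.1, 2.5),
      pdf_coherences = c(0.10, 0.50)
    )
  )
  p <- presets[[label]]
  if (is.null(p)) {
    stop("unknown preset: must be one of ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  structure(c(list(label = label, n_per_coherence = n_per_coherence), p),
            class = "species_preset")
}

#' Generate a synthetic behavioral dataset from a preset
#'
#' Simulates `n_per_coherence` trials at each coherence of the preset's
#' grid with [simulate_trials()] and concatenates them into one trial
#' table tagged with the preset label and seed. Deterministic per seed.
#'
#' @param preset A [species_preset()].
#' @param seed Integer seed.
#' @param grid A [solver_grid()].
#' @return A trial table ([tibble::tibble()]) with columns `subject`,
#'   `coherence`, `correct`, `rt`, `decided`, and attributes `species`
#'   and `seed`.
#' @export
generate_dataset <- function(preset, seed, grid = solver_grid()) {
  stopifnot(inherits(preset, "species_preset"))
  set.seed(seed)
  tabs <- lapply(preset$coherences, function(cc) {
    simulate_trials(preset$spec, cc, preset$n_per_coherence, seed = NULL,
                    grid = grid)
  })
  out <- dplyr::bind_rows(tabs)
  out <- tibble::add_column(out, subject = "sim", .before = 1)
  attr(out, "species") <- preset$label
  attr(out, "seed") <- seed
  attr(out, "filters") <- character()
  out
}

#' Filter a trial table to an RT analysis window
#'
#' Retains decided trials with `lo <= rt <= hi` (both ends closed),
#' preserving order; undecided trials and out-of-window RTs are dropped.
#' The number removed is recorded in the table's `filters` provenance
#' attribute and reported as a message. Idempotent.
#'
#' @param trials Trial table.
#' @param lo,hi Window bounds in seconds, `lo < hi`.
#' @param quiet Suppress the removal message.
#' @return The filtered trial table.
#' @export
filter_rt_window <- function(trials, lo, hi, quiet = FALSE) {
  stopifnot(is.data.frame(trials), lo < hi)
  decided <- if ("decided" %in% names(trials)) trials$decided else TRUE
  keep <- decided & !is.na(trials$rt) & trials$rt >= lo & trials$rt <= hi
  removed <- sum(!keep)
  out <- trials[keep, , drop = FALSE]
  prov <- c(attr(trials, "filters"),
            sprintf("rt_window[%g,%g]: removed %d of %d trials", lo, hi,
                    removed, nrow(trials)))
  attr(out, "filters") <- prov
  attr(out, "species") <- attr(trials, "species")
  attr(out, "seed") <- attr(trials, "seed")
  if (!quiet) message(prov[length(prov)])
  out
}
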