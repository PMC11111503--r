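as_group_list <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  if (any(vapply(groups, length, 1L) == 0)) {
    stop("each group must be non-empty", call. = FALSE)
  }
  groups
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' `g - 1` degrees of freedom (wraps [stats::kruskal.test()]). When all
#' observations are identical the statistic is defined as 0 with p = 1.
#'
#' @param groups A list of two or more numeric vectors.
#' @return A list with elements `H`, `p_value`, `df`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need at least 3 observations in total", call. = FALSE)
  if (length(unique(x)) == 1) {
    return(list(H = 0, p_value = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' All pairwise mean differences with studentized-range adjusted p-values
#' (family-wise control at the chosen level), via
#' [stats::TukeyHSD()] on a one-way [stats::aov()] fit. Singleton groups
#' are rejected (no within-group variance).
#'
#' @param groups A list of two or more numeric vectors (each of length
#'   `>= 2`).
#' @param conf_level Family-wise confidence level (default 0.95).
#' @return A tibble with one row per pair: `pair`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  groups <- as_group_list(groups)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("each group needs >= 2 observations for Tukey HSD", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups))
  )
  hsd <- stats::TukeyHSD(stats::aov(value ~ group, data = df),
                         conf.level = conf_level)$group
  tibble::tibble(
    pair = rownames(hsd),
    diff = hsd[, "diff"],
    lwr = hsd[, "lwr"],
    upr = hsd[, "upr"],
    p_adj = hsd[, "p adj"]
  )
}

#' Normalized parameter matrix across cases
#'
#' Min-max normalizes each of the seven free parameters across the
#' supplied best-run specifications, so every parameter lies in \[0, 1\]
#' for plotting. A parameter that is constant across cases maps to 0.5.
#'
#' @param best_specs A named list (case label -> [model_spec()]), length
#'   `>= 2`.
#' @return A numeric matrix, cases x parameters, values in \[0, 1\].
#' @export
normalize_params <- function(best_specs) {
  stopifnot(is.list(best_specs), length(best_specs) >= 2)
  raw <- do.call(rbind, lapply(best_specs, free_params))
  rownames(raw) <- names(best_specs)
  apply(raw, 2, function(p) {
    r <- max(p) - min(p)
    if (r == 0) rep(0.5, length(p)) else (p - min(p)) / r
  })
}

#' Compare fitted model cases
#'
#' Assembles the per-case squared-error and AIC distributions over runs,
#' runs the Kruskal-Wallis omnibus test and Tukey HSD pairwise comparisons
#' on each, ranks the cases by mean squared error over runs (the best
#' fitted case is the lowest; ties are stable-sorted by case label), and
#' reports the min-max normalized parameters of each case's best run.
#'
#' @param fits A named list (case label -> [fit_case()] result), length
#'   `>= 2`.
#' @return An object of class `"ddm_comparison"`: list with
#'   `sq_error_samples`, `aic_samples`, `kruskal_sq_error`, `kruskal_aic`,
#'   `tukey_sq_error`, `tukey_aic`, `ranking` (tibble: `case`,
#'   `mean_sq_error`, `mean_aic`, `rank`), `normalized_params`,
#'   `best_case`.
#' @export
compare_cases <- function(fits) {
  stopifnot(is.list(fits))
  if (length(fits) < 2) stop("need at least 2 fitted cases", call. = FALSE)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$case$label, "")
  }
  sq <- lapply(fits, function(f) f$runs$sq_error)
  ai <- lapply(fits, function(f) f$runs$aic)
  ranking <- tibble::tibble(
    case = names(fits),
    mean_sq_error = vapply(sq, mean, 1),
    mean_aic = vapply(ai, mean, 1)
  )
  ord <- order(ranking$mean_sq_error, ranking$case)
  ranking <- ranking[ord, ]
  ranking$rank <- seq_len(nrow(ranking))
  best_specs <- lapply(fits, function(f) f$best_spec)
  structure(list(
    sq_error_samples = sq,
    aic_samples = ai,
    kruskal_sq_error = kruskal_wallis(sq),
    kruskal_aic = kruskal_wallis(ai),
    tukey_sq_error = tukey_hsd(sq),
    tukey_aic = tukey_hsd(ai),
    ranking = ranking,
    normalized_params = normalize_params(best_specs),
    best_case = ranking$case[1]
  ), class = "ddm_comparison")
}

#' @export
print.ddm_comparison <- function(x, ...) {
  cat("<ddm_comparison>\n")
  cat(sprintf("  best case by mean squared error: %s\n", x$best_case))
  cat(sprintf("  Kruskal-Wallis on squared errors: H = %.3f, p = %.3g\n",
              x$kruskal_sq_error$H, x$kruskal_sq_error$p_value))
  cat(sprintf("  Kruskal-Wallis on AICs: H = %.3f, p = %.3g\n",
              x$kruskal_aic$H, x$kruskal_aic$p_value))
  print(x$ranking)
  invisible(x)
}

#' Export a comparison report
#'
#' Writes the full report as JSON, or a human-readable text summary.
#'
#' @param report A [compare_cases()] result.
#' @param path Output path ending in `.json` or `.txt`.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  stopifnot(inherits(report, "ddm_comparison"))
  if (grepl("\\.json$", path)) {
    doc <- list(
      ranking = report$ranking,
      kruskal_sq_error = report$kruskal_sq_error,
      kruskal_aic = report$kruskal_aic,
      tukey_sq_error = report$tukey_sq_error,
      tukey_aic = report$tukey_aic,
      sq_error_samples = report$sq_error_samples,
      aic_samples = report$aic_samples,
      normalized_params = as.data.frame(report$normalized_params)
    )
    jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
  }
  invisible(path)
}
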