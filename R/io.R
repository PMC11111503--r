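#' Column dialect for reading trial tables
#'
#' Maps the column names and units of a CSV file onto the package's trial
#' table schema. Times are normalized to seconds at the read boundary
#' (milliseconds accepted via `rt_unit = "ms"`); coherences given as
#' percentages are divided by 100.
#'
#' @param coherence,correct,rt Source column names.
#' @param subject Optional subject-id column name.
#' @param decided Optional decided-flag column name (all rows decided when
#'   absent).
#' @param rt_unit `"s"` or `"ms"`.
#' @param coherence_unit `"fraction"` or `"percent"`.
#' @return A list of class `"trial_dialect"`.
#' @export
trial_dialect <- function(coherence = "coherence", correct = "correct",
                          rt = "rt", subject = NULL, decided = NULL,
                          rt_unit = c("s", "ms"),
                          coherence_unit = c("fraction", "percent")) {
  structure(list(coherence = coherence, correct = correct, rt = rt,
                 subject = subject, decided = decided,
                 rt_unit = match.arg(rt_unit),
                 coherence_unit = match.arg(coherence_unit)),
            class = "trial_dialect")
}

#' Read a trial table from CSV
#'
#' Reads one record per trial (coherence, correctness, response time),
#' applies the dialect's column mapping and unit conversions, validates
#' rows, and returns a tidy trial table. Rows with unparseable or invalid
#' values (non-finite coherence, |c| > 1 after conversion, non-positive RT
#' on a decided trial) are rejected; their line numbers are reported in
#' the `rejected` attribute and as a message.
#'
#' @param path CSV file with a header row.
#' @param dialect A [trial_dialect()].
#' @param quiet Suppress the rejection message.
#' @return A trial table tibble with columns `subject`, `coherence`
#'   (fraction), `correct` (logical), `rt` (seconds), `decided`.
#' @export
read_trials <- function(path, dialect = trial_dialect(), quiet = FALSE) {
  stopifnot(inherits(dialect, "trial_dialect"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty trial table: ", path, call. = FALSE)
  need <- c(dialect$coherence, dialect$correct, dialect$rt)
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  coh <- suppressWarnings(as.numeric(raw[[dialect$coherence]]))
  if (dialect$coherence_unit == "percent") coh <- coh / 100
  rt <- suppressWarnings(as.numeric(raw[[dialect$rt]]))
  if (dialect$rt_unit == "ms") rt <- rt / 1000
  correct <- as.logical(raw[[dialect$correct]])
  decided <- if (!is.null(dialect$decided) && dialect$decided %in% names(raw)) {
    as.logical(raw[[dialect$decided]])
  } else {
    rep(TRUE, nrow(raw))
  }
  subject <- if (!is.null(dialect$subject) && dialect$subject %in% names(raw)) {
    as.character(raw[[dialect$subject]])
  } else {
    rep("s1", nrow(raw))
  }
  ok <- is.finite(coh) & abs(coh) <= 1 & !is.na(correct) & !is.na(decided) &
    (!decided | (is.finite(rt) & rt > 0))
  rejected <- which(!ok)
  if (length(rejected) > 0 && !quiet) {
    message(sprintf("rejected %d invalid row(s) at lines: %s",
                    length(rejected),
                    paste(utils::head(rejected + 1, 20), collapse = ", ")))
  }
  out <- tibble::tibble(
    subject = subject[ok], coherence = coh[ok], correct = correct[ok],
    rt = rt[ok], decided = decided[ok]
  )
  if (nrow(out) == 0) stop("no valid trials in ", path, call. = FALSE)
  attr(out, "rejected") <- rejected
  attr(out, "filters") <- sprintf("read_trials: rejected %d row(s)",
                                  length(rejected))
  out
}

#' Write a trial table to CSV
#'
#' Seconds and coherence fractions, matching the [read_trials()] default
#' dialect, so write-then-read round-trips.
#'
#' @param trials Trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- intersect(c("subject", "coherence", "correct", "rt", "decided"),
                    names(trials))
  utils::write.csv(as.data.frame(trials)[, cols], path, row.names = FALSE)
  invisible(path)
}
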