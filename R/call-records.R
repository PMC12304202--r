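#' Construct a canonical call table
#'
#' The canonical in-memory representation of detected USVs is a tibble with
#' one row per call and a fixed unit convention: clock times in seconds from
#' recording start (half-open intervals `[onset, offset)`), durations in
#' milliseconds, frequencies in kHz, slopes in kHz/s.  All readers convert
#' into this layout once; no other module performs unit conversion.
#'
#' @param onset,offset Call boundaries, seconds from recording start.
#' @param peak_frequency Peak frequency (frequency at the maximum-amplitude
#'   point of the call), kHz.
#' @param bandwidth Highest minus lowest call frequency, kHz.
#' @param slope Frequency-contour slope, kHz/s (`NA` until contour-based
#'   features are available).
#' @param cluster Integer cluster label 1-8, or `NA` for unassigned.
#' @param source_id Opaque identifier linking back to the input row.
#' @param peak_approximate Logical; `TRUE` when the peak frequency was
#'   approximated (e.g. band midpoint) rather than measured.
#'
#' @return A tibble of class `usv_calls`, sorted by onset.
#' @export
call_table <- function(onset = numeric(), offset = numeric(),
                       peak_frequency = numeric(), bandwidth = numeric(),
                       slope = NA_real_, cluster = NA_integer_,
                       source_id = NA_character_, peak_approximate = FALSE) {
  n <- length(onset)
  tb <- tibble::tibble(
    onset = as.numeric(onset),
    offset = as.numeric(offset),
    duration = (as.numeric(offset) - as.numeric(onset)) * 1000,
    peak_frequency = rep_len(as.numeric(peak_frequency), n),
    bandwidth = rep_len(as.numeric(bandwidth), n),
    slope = rep_len(as.numeric(slope), n),
    cluster = rep_len(as.integer(cluster), n),
    source_id = rep_len(as.character(source_id), n),
    peak_approximate = rep_len(as.logical(peak_approximate), n)
  )
  tb <- tb[order(tb$onset), , drop = FALSE]
  validate_call_table(tb)
  class(tb) <- c("usv_calls", class(tb))
  tb
}

validate_call_table <- function(calls) {
  if (nrow(calls) == 0L) return(invisible(calls))
  bad <- which(calls$offset <= calls$onset)
  assert_that(length(bad) == 0L,
              "offset must exceed onset; violated at row(s) ",
              paste(utils::head(bad, 5L), collapse = ", "),
              class = "pupsyntax_validation_error")
  assert_that(all(abs(calls$duration - (calls$offset - calls$onset) * 1000) < 0.01),
              "duration inconsistent with onset/offset beyond 0.01 ms",
              class = "pupsyntax_validation_error")
  assert_that(all(calls$bandwidth >= 0, na.rm = TRUE),
              "bandwidth must be non-negative",
              class = "pupsyntax_validation_error")
  assert_that(all(calls$peak_frequency > 0, na.rm = TRUE),
              "peak_frequency must be positive",
              class = "pupsyntax_validation_error")
  assert_that(!is.unsorted(calls$onset),
              "calls must be sorted by onset",
              class = "pupsyntax_validation_error")
  invisible(calls)
}

#' Recording phases
#'
#' Session phases are an enum, not free text: three developmental
#' time points (postnatal days 6, 9, 12) and the two isolation phases of the
#' maternal potentiation test on postnatal day 10.
#' @export
USV_PHASES <- c("DEV6", "DEV9", "DEV12", "ISO1", "ISO2")

phase_pnd <- function(phase) {
  c(DEV6 = 6L, DEV9 = 9L, DEV12 = 12L, ISO1 = 10L, ISO2 = 10L)[[phase]]
}

#' Construct a recording
#'
#' A recording is one subject-session: an ordered call train plus the
#' metadata needed by the experimental designs (treatment group, sex,
#' litter, postnatal day, phase, session duration).
#'
#' @param calls A call table from [call_table()] (or a compatible tibble).
#' @param subject_id,litter_id Identifiers (character scalars).
#' @param sex `"F"` or `"M"`.
#' @param group Treatment group, `"VEH"` (control) or `"MAM"`.
#' @param phase One of [USV_PHASES].
#' @param pnd Postnatal day; defaults to the day implied by `phase`.
#' @param duration Session length, seconds.
#'
#' @return An object of class `usv_recording`.
#' @export
recording <- function(calls, subject_id, litter_id = NA_character_,
                      sex = c("F", "M"), group = c("VEH", "MAM"),
                      phase = "DEV6", pnd = NULL, duration = 300) {
  sex <- match.arg(sex)
  group <- match.arg(group)
  phase <- match.arg(phase, USV_PHASES)
  pnd <- pnd %||% phase_pnd(phase)
  if (phase %in% c("ISO1", "ISO2")) {
    assert_that(pnd == 10L, "phases ISO1/ISO2 imply postnatal day 10")
  }
  validate_call_table(calls)
  if (nrow(calls) > 0L) {
    assert_that(all(calls$offset <= duration + 1e-9),
                "call offsets exceed the recording duration",
                class = "pupsyntax_validation_error")
  }
  structure(
    list(subject_id = as.character(subject_id),
         litter_id = as.character(litter_id),
         sex = sex, group = group, pnd = as.integer(pnd), phase = phase,
         duration = as.numeric(duration), calls = calls),
    class = "usv_recording")
}

#' @export
print.usv_recording <- function(x, ...) {
  cat(sprintf("<usv_recording> subject %s (%s, %s, litter %s), phase %s (PND %d)\n",
              x$subject_id, x$group, x$sex, x$litter_id, x$phase, x$pnd))
  cat(sprintf("  %d calls over %.0f s\n", nrow(x$calls), x$duration))
  invisible(x)
}

#' Construct a cohort
#'
#' A cohort bundles recordings with a label and enforces the design-level
#' invariants: `(subject_id, phase)` pairs are unique and every litter
#' belongs to exactly one treatment group.
#'
#' @param recordings List of [recording()] objects.
#' @param label Cohort label.
#' @return An object of class `usv_cohort`.
#' @export
cohort <- function(recordings, label = "cohort") {
  assert_that(all(vapply(recordings, inherits, logical(1), "usv_recording")),
              "all elements must be usv_recording objects")
  keys <- vapply(recordings, function(r) paste(r$subject_id, r$phase), "")
  assert_that(!anyDuplicated(keys),
              "duplicate (subject_id, phase) pairs in cohort",
              class = "pupsyntax_consistency_error")
  lit <- data.frame(
    litter = vapply(recordings, function(r) r$litter_id, ""),
    group = vapply(recordings, function(r) r$group, ""))
  lit <- unique(lit[!is.na(lit$litter), ])
  dup <- lit$litter[duplicated(lit$litter)]
  assert_that(length(dup) == 0L,
              "litter(s) assigned to more than one group: ",
              paste(unique(dup), collapse = ", "),
              class = "pupsyntax_consistency_error")
  structure(list(recordings = recordings, label = label), class = "usv_cohort")
}

#' @export
print.usv_cohort <- function(x, ...) {
  cat(sprintf("<usv_cohort> '%s': %d recordings\n", x$label, length(x$recordings)))
  print(summarize_cohort(x))
  invisible(x)
}

#' @export
length.usv_cohort <- function(x) length(x$recordings)

#' Summarize a cohort by group and sex
#'
#' Counts recordings and calls by treatment group and sex (the layout used
#' to report cohort composition) and call totals by phase.
#'
#' @param x A `usv_cohort`.
#' @return A list with tibbles `by_group_sex` and `by_phase`.
#' @export
summarize_cohort <- function(x) {
  assert_that(inherits(x, "usv_cohort"), "x must be a usv_cohort")
  meta <- tibble::tibble(
    group = vapply(x$recordings, function(r) r$group, ""),
    sex = vapply(x$recordings, function(r) r$sex, ""),
    phase = vapply(x$recordings, function(r) r$phase, ""),
    n_calls = vapply(x$recordings, function(r) nrow(r$calls), 0L))
  by_gs <- stats::aggregate(cbind(n_recordings = rep(1L, nrow(meta)),
                                  n_calls = meta$n_calls),
                            by = list(group = meta$group, sex = meta$sex), FUN = sum)
  by_ph <- stats::aggregate(cbind(n_recordings = rep(1L, nrow(meta)),
                                  n_calls = meta$n_calls),
                            by = list(phase = meta$phase), FUN = sum)
  list(by_group_sex = tibble::as_tibble(by_gs),
       by_phase = tibble::as_tibble(by_ph))
}

#' Total calls per phase from a count table
#'
#' Utility for consistency checks on published per-day call totals: given a
#' table with columns `phase` and `n_calls`, returns per-phase totals and
#' the pooled total, as used e.g. to confirm that a pooled
#' clustering-training set equals the sum of its per-day counts.
#'
#' @param counts Data frame with columns `phase` and `n_calls`.
#' @return A list with `by_phase` (tibble) and `total` (numeric scalar).
#' @export
phase_call_totals <- function(counts) {
  assert_that(all(c("phase", "n_calls") %in% names(counts)),
              "counts must have columns 'phase' and 'n_calls'",
              class = "pupsyntax_format_error")
  agg <- stats::aggregate(list(n_calls = counts$n_calls),
                          by = list(phase = counts$phase), FUN = sum)
  list(by_phase = tibble::as_tibble(agg), total = sum(counts$n_calls))
}
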