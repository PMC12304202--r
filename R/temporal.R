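# Temporal organisation: inter-call intervals, sequences, bouts.
#
# The interval taxonomy uses closed lower bounds ("at least"): a gap of
# >= 150 ms starts a new sequence and a gap of >= 2000 ms starts a new
# bout, so a gap of exactly 150 ms is between-sequence and exactly
# 2000 ms is between-bout.  Because clock times are doubles, "at least"
# is evaluated with a 1e-9 ms guard so a nominally exact boundary gap is
# never misclassified by floating-point rounding.

EPS_GAP_MS <- 1e-9

#' Inter-call interval thresholds
#'
#' @param call_gap_min_ms Shortest meaningful gap between distinct calls,
#'   ms (default 10; shorter gaps are merged at I/O).
#' @param sequence_gap_ms Gaps at least this long separate sequences
#'   (default 150 ms).
#' @param bout_gap_ms Gaps at least this long separate bouts
#'   (default 2000 ms).
#' @return A list of class `interval_thresholds`.
#' @export
interval_thresholds <- function(call_gap_min_ms = 10, sequence_gap_ms = 150,
                                bout_gap_ms = 2000) {
  assert_that(call_gap_min_ms < sequence_gap_ms && sequence_gap_ms < bout_gap_ms,
              "thresholds must satisfy call_gap < sequence_gap < bout_gap")
  structure(list(call_gap_min_ms = call_gap_min_ms,
                 sequence_gap_ms = sequence_gap_ms,
                 bout_gap_ms = bout_gap_ms),
            class = "interval_thresholds")
}

.gaps_ms <- function(calls) {
  n <- nrow(calls)
  if (n < 2L) return(numeric())
  (calls$onset[-1L] - calls$offset[-n]) * 1000
}

#' Inter-call intervals and their classes
#'
#' The inter-call interval is the time from one call's end to the next
#' call's onset.  Each gap is classed `WITHIN_SEQUENCE` (< 150 ms),
#' `BETWEEN_SEQUENCE` (150 to < 2000 ms) or `BETWEEN_BOUT` (>= 2000 ms).
#'
#' @param rec A [recording()] (or a call table).
#' @param thresholds An [interval_thresholds()].
#' @return Tibble with `gap_ms` and `class` (`n_calls - 1` rows).
#' @export
inter_call_intervals <- function(rec, thresholds = interval_thresholds()) {
  calls <- if (inherits(rec, "usv_recording")) rec$calls else rec
  assert_that(!is.unsorted(calls$onset), "calls must be sorted by onset",
              class = "pupsyntax_validation_error")
  g <- .gaps_ms(calls)
  if (any(g < thresholds$call_gap_min_ms)) {
    warn_ps(sum(g < thresholds$call_gap_min_ms),
            " gap(s) below the ", thresholds$call_gap_min_ms,
            " ms minimum; consider merge_close_calls()")
  }
  cls <- ifelse(g >= thresholds$bout_gap_ms - EPS_GAP_MS, "BETWEEN_BOUT",
                ifelse(g >= thresholds$sequence_gap_ms - EPS_GAP_MS,
                       "BETWEEN_SEQUENCE", "WITHIN_SEQUENCE"))
  tibble::tibble(gap_ms = g, class = cls)
}

#' Segment a call train into sequences and bouts
#'
#' A new sequence starts at every gap of at least `sequence_gap_ms`; a new
#' bout at every gap of at least `bout_gap_ms`.  Sequences partition the
#' call indices in order, bouts partition the sequence indices, and every
#' bout boundary coincides with a sequence boundary (a between-bout gap is
#' also a between-sequence gap since the thresholds are nested).
#'
#' @inheritParams inter_call_intervals
#' @return A list of class `usv_segmentation`: `sequences` (tibble
#'   `sequence`, `first_call`, `last_call`, `bout`), `bouts` (tibble
#'   `bout`, `first_sequence`, `last_sequence`), and per-call index
#'   vectors `call_sequence`, `call_bout`.  Zero calls give an empty
#'   segmentation.
#' @examples
#' onset <- c(0, 0.1, 0.4, 0.5, 3.6, 3.7)   # gaps: 50, 250, 50, 3050, 50 ms
#' calls <- call_table(onset = onset, offset = onset + 0.05,
#'                     peak_frequency = 38, bandwidth = 3)
#' seg <- segment_calls(calls)
#' seg$call_sequence   # 1 1 2 2 3 3
#' seg$call_bout       # 1 1 1 1 2 2
#' @export
segment_calls <- function(rec, thresholds = interval_thresholds()) {
  calls <- if (inherits(rec, "usv_recording")) rec$calls else rec
  n <- nrow(calls)
  if (n == 0L) {
    return(structure(list(
      sequences = tibble::tibble(sequence = integer(), first_call = integer(),
                                 last_call = integer(), bout = integer()),
      bouts = tibble::tibble(bout = integer(), first_sequence = integer(),
                             last_sequence = integer()),
      call_sequence = integer(), call_bout = integer(),
      thresholds = thresholds), class = "usv_segmentation"))
  }
  assert_that(!is.unsorted(calls$onset), "calls must be sorted by onset",
              class = "pupsyntax_validation_error")
  g <- .gaps_ms(calls)
  call_seq <- cumsum(c(1L, as.integer(g >= thresholds$sequence_gap_ms - EPS_GAP_MS)))
  call_bout <- cumsum(c(1L, as.integer(g >= thresholds$bout_gap_ms - EPS_GAP_MS)))
  seq_ids <- unique(call_seq)
  sequences <- tibble::tibble(
    sequence = seq_ids,
    first_call = vapply(seq_ids, function(s) min(which(call_seq == s)), 1L),
    last_call = vapply(seq_ids, function(s) max(which(call_seq == s)), 1L))
  sequences$bout <- call_bout[sequences$first_call]
  bout_ids <- unique(sequences$bout)
  bouts <- tibble::tibble(
    bout = bout_ids,
    first_sequence = vapply(bout_ids, function(b) min(sequences$sequence[sequences$bout == b]), 1L),
    last_sequence = vapply(bout_ids, function(b) max(sequences$sequence[sequences$bout == b]), 1L))
  structure(list(sequences = sequences, bouts = bouts,
                 call_sequence = call_seq, call_bout = call_bout,
                 thresholds = thresholds),
            class = "usv_segmentation")
}

#' @export
print.usv_segmentation <- function(x, ...) {
  cat(sprintf("<usv_segmentation> %d calls in %d sequences, %d bouts\n",
              length(x$call_sequence), nrow(x$sequences), nrow(x$bouts)))
  invisible(x)
}

#' Per-recording temporal summary
#'
#' Latency to the first call (ms, from recording start to first onset),
#' mean inter-call interval over all gaps regardless of class (restrict to
#' within-sequence gaps with `ici_within_only`), sequence and bout counts,
#' mean calls per sequence and sequences per bout (ratios of totals), and
#' per-minute call counts by onset bin (a call spanning a bin edge counts
#' once, in its onset bin).
#'
#' Recordings without calls get counts of zero and missing latency and
#' mean inter-call interval, plus a `no_calls` flag (such animals are
#' typically excluded from latency analyses).
#'
#' @param rec A [recording()].
#' @param seg A [segment_calls()] result for `rec` (computed if `NULL`).
#' @param bin_width_s Width of the per-minute bins, seconds (default 60).
#' @param ici_within_only Restrict mean inter-call interval to
#'   within-sequence gaps (default `FALSE`).
#' @param thresholds An [interval_thresholds()].
#' @return One-row tibble with `n_calls`, `latency_ms`, `mean_ici_ms`,
#'   `n_sequences`, `mean_calls_per_sequence`, `n_bouts`,
#'   `mean_sequences_per_bout`, `no_calls`, and a `per_minute_counts`
#'   list-column.
#' @export
temporal_summary <- function(rec, seg = NULL, bin_width_s = 60,
                             ici_within_only = FALSE,
                             thresholds = interval_thresholds()) {
  assert_that(inherits(rec, "usv_recording"), "rec must be a usv_recording")
  seg <- seg %||% segment_calls(rec, thresholds)
  calls <- rec$calls
  n <- nrow(calls)
  n_bins <- max(1L, ceiling(rec$duration / bin_width_s))
  if (n == 0L) {
    return(tibble::tibble(
      n_calls = 0L, latency_ms = NA_real_, mean_ici_ms = NA_real_,
      n_sequences = 0L, mean_calls_per_sequence = NA_real_,
      n_bouts = 0L, mean_sequences_per_bout = NA_real_, no_calls = TRUE,
      per_minute_counts = list(rep(0L, n_bins))))
  }
  assert_that(length(seg$call_sequence) == n,
              "segmentation inconsistent with recording")
  ici <- inter_call_intervals(calls, thresholds)
  gaps <- if (ici_within_only) ici$gap_ms[ici$class == "WITHIN_SEQUENCE"] else ici$gap_ms
  bins <- pmin(floor(calls$onset / bin_width_s) + 1L, n_bins)
  pmc <- tabulate(bins, nbins = n_bins)
  tibble::tibble(
    n_calls = n,
    latency_ms = calls$onset[1L] * 1000,
    mean_ici_ms = if (length(gaps)) mean(gaps) else NA_real_,
    n_sequences = nrow(seg$sequences),
    mean_calls_per_sequence = n / nrow(seg$sequences),
    n_bouts = nrow(seg$bouts),
    mean_sequences_per_bout = nrow(seg$sequences) / nrow(seg$bouts),
    no_calls = FALSE,
    per_minute_counts = list(pmc))
}
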