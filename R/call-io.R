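# Readers and writers for call tables and cohort manifests.
#
# Unit policy: Raven selection tables carry Hz and seconds; DeepSqueak-style
# CSVs carry kHz and seconds.  Everything is converted to the canonical
# layout (kHz / ms / s) here and nowhere else.

RAVEN_REQUIRED <- c("Begin Time (s)", "End Time (s)", "Low Freq (Hz)", "High Freq (Hz)")

# Normalise a header name for synonym matching: lowercase, alphanumerics only.
.norm_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.find_col <- function(nms, synonyms) {
  hit <- which(.norm_name(nms) %in% .norm_name(synonyms))
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

.check_times <- function(begin, end, path) {
  bad <- which(!is.finite(begin) | !is.finite(end) | begin < 0 | end <= begin)
  if (length(bad) > 0L) {
    stop_ps("invalid times (negative, non-finite, or End <= Begin) in '", path,
            "' at data row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
            class = "pupsyntax_validation_error")
  }
}

.warn_overlaps <- function(calls, path) {
  if (nrow(calls) > 1L && any(calls$onset[-1L] < calls$offset[-nrow(calls)])) {
    warn_ps("overlapping detections in '", path,
            "'; kept as-is (merge with merge_close_calls() or at cohort load)")
  }
  calls
}

#' Read a Raven selection table
#'
#' Parses the tab-delimited selection-table format exported by Raven
#' (columns `Selection`, `View`, `Channel`, `Begin Time (s)`,
#' `End Time (s)`, `Low Freq (Hz)`, `High Freq (Hz)`, optionally
#' `Peak Freq (Hz)`).  Frequencies are converted from Hz to kHz;
#' `bandwidth = (High - Low) / 1000`.  When no peak-frequency column is
#' present the Low/High midpoint is used and the call is flagged
#' `peak_approximate` (classification refuses flagged calls unless told
#' otherwise, since peak frequency enters every cluster rule).
#' Annotation columns `Slope (kHz/s)` and `Cluster`, if present, are read
#' back into the corresponding fields.
#'
#' Overlapping or near-duplicate detections are kept and flagged with a
#' warning; the 10 ms merge rule is applied at cohort load
#' (see [load_cohort()] and [merge_close_calls()]).
#'
#' @param path Path to the selection table.
#' @param recording_metadata Named list passed on to [recording()]
#'   (`subject_id`, `litter_id`, `sex`, `group`, `phase`, `pnd`, `duration`).
#' @return A [recording()].
#' @export
read_raven_selection_table <- function(path, recording_metadata = list(subject_id = "unknown")) {
  assert_that(file.exists(path), "file not found: ", path, class = "pupsyntax_io_error")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(RAVEN_REQUIRED, names(df))
  assert_that(length(missing) == 0L,
              "missing mandatory column(s) in '", path, "': ",
              paste(missing, collapse = ", "),
              class = "pupsyntax_format_error")
  if (nrow(df) == 0L) {
    calls <- call_table()
  } else {
    begin <- as.numeric(df[["Begin Time (s)"]])
    end <- as.numeric(df[["End Time (s)"]])
    .check_times(begin, end, path)
    lo <- as.numeric(df[["Low Freq (Hz)"]]) / 1000
    hi <- as.numeric(df[["High Freq (Hz)"]]) / 1000
    assert_that(all(hi >= lo), "High Freq below Low Freq in '", path, "'",
                class = "pupsyntax_validation_error")
    pk_col <- .find_col(names(df), c("Peak Freq (Hz)", "PeakFreq"))
    if (!is.na(pk_col)) {
      peak <- as.numeric(df[[pk_col]]) / 1000
      approx <- FALSE
    } else {
      peak <- (lo + hi) / 2
      approx <- TRUE
    }
    slope_col <- .find_col(names(df), c("Slope (kHz/s)"))
    slope <- if (!is.na(slope_col)) as.numeric(df[[slope_col]]) else NA_real_
    clus_col <- .find_col(names(df), "Cluster")
    clus <- if (!is.na(clus_col)) as.integer(df[[clus_col]]) else NA_integer_
    sel <- if ("Selection" %in% names(df)) as.character(df$Selection) else as.character(seq_len(nrow(df)))
    calls <- call_table(onset = begin, offset = end, peak_frequency = peak,
                        bandwidth = hi - lo, slope = slope, cluster = clus,
                        source_id = sel, peak_approximate = approx)
    calls <- .warn_overlaps(calls, path)
  }
  do.call(recording, c(list(calls = calls), recording_metadata))
}

#' Read a DeepSqueak-style call CSV
#'
#' Parses comma-delimited call tables with (case-insensitive, synonym
#' tolerant) columns for begin time (s), call duration (s), principal/peak
#' frequency (kHz) and bandwidth (kHz); unknown extra columns are ignored.
#' When an end-time column is also present it wins over the duration column
#' if the two disagree by more than 1 ms (with a warning).
#'
#' @inheritParams read_raven_selection_table
#' @return A [recording()].
#' @export
read_deepsqueak_csv <- function(path, recording_metadata = list(subject_id = "unknown")) {
  assert_that(file.exists(path), "file not found: ", path, class = "pupsyntax_io_error")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- list(
    begin = c("Begin Time (s)", "BeginTime", "Start Time (s)"),
    dur = c("Call Length (s)", "Duration (s)", "CallLength"),
    peak = c("Principal Frequency (kHz)", "PeakFreq", "Peak Frequency (kHz)"),
    bw = c("Delta Freq (kHz)", "Bandwidth (kHz)", "DeltaFreq"))
  idx <- lapply(cols, .find_col, nms = names(df))
  missing <- names(idx)[vapply(idx, is.na, TRUE)]
  assert_that(length(missing) == 0L,
              "missing mandatory column(s) in '", path, "': ",
              paste(vapply(cols[missing], `[`, "", 1L), collapse = ", "),
              class = "pupsyntax_format_error")
  if (nrow(df) == 0L) {
    calls <- call_table()
  } else {
    begin <- as.numeric(df[[idx$begin]])
    dur_s <- as.numeric(df[[idx$dur]])
    end_col <- .find_col(names(df), c("End Time (s)", "EndTime"))
    if (!is.na(end_col)) {
      end <- as.numeric(df[[end_col]])
      disagree <- abs((end - begin) - dur_s) > 1e-3
      if (any(disagree, na.rm = TRUE)) {
        warn_ps("duration column disagrees with begin/end times by > 1 ms in '",
                path, "' at ", sum(disagree), " row(s); times win")
      }
    } else {
      end <- begin + dur_s
    }
    .check_times(begin, end, path)
    slope_col <- .find_col(names(df), c("Slope (kHz/s)"))
    slope <- if (!is.na(slope_col)) as.numeric(df[[slope_col]]) else NA_real_
    clus_col <- .find_col(names(df), "Cluster")
    clus <- if (!is.na(clus_col)) as.integer(df[[clus_col]]) else NA_integer_
    id_col <- .find_col(names(df), c("ID", "Selection"))
    ids <- if (!is.na(id_col)) as.character(df[[id_col]]) else as.character(seq_len(nrow(df)))
    calls <- call_table(onset = begin, offset = end,
                        peak_frequency = as.numeric(df[[idx$peak]]),
                        bandwidth = as.numeric(df[[idx$bw]]),
                        slope = slope, cluster = clus, source_id = ids,
                        peak_approximate = FALSE)
    calls <- .warn_overlaps(calls, path)
  }
  do.call(recording, c(list(calls = calls), recording_metadata))
}

#' Write a call table
#'
#' Serialises a recording's calls in either the Raven selection-table
#' dialect (tab-delimited, Hz/seconds, standard column names, plus
#' `Slope (kHz/s)` and `Cluster` annotation columns) or the call-CSV
#' dialect (comma-delimited, kHz/seconds).  Both round-trip through the
#' matching reader to at least six decimal places.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param dialect `"raven"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(rec, path, dialect = c("raven", "csv")) {
  dialect <- match.arg(dialect)
  assert_that(inherits(rec, "usv_recording"), "rec must be a usv_recording")
  calls <- rec$calls
  if (dialect == "raven") {
    out <- data.frame(
      Selection = if (nrow(calls)) seq_len(nrow(calls)) else integer(),
      View = rep("Spectrogram 1", nrow(calls)),
      Channel = rep(1L, nrow(calls)),
      `Begin Time (s)` = calls$onset,
      `End Time (s)` = calls$offset,
      `Low Freq (Hz)` = (calls$peak_frequency - calls$bandwidth / 2) * 1000,
      `High Freq (Hz)` = (calls$peak_frequency + calls$bandwidth / 2) * 1000,
      `Peak Freq (Hz)` = calls$peak_frequency * 1000,
      `Slope (kHz/s)` = calls$slope,
      Cluster = calls$cluster,
      check.names = FALSE)
    ok <- tryCatch({
      utils::write.table(format(out, digits = 15, scientific = FALSE, trim = TRUE),
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
  } else {
    out <- data.frame(
      ID = calls$source_id,
      `Begin Time (s)` = calls$onset,
      `End Time (s)` = calls$offset,
      `Call Length (s)` = calls$duration / 1000,
      `Principal Frequency (kHz)` = calls$peak_frequency,
      `Delta Freq (kHz)` = calls$bandwidth,
      `Slope (kHz/s)` = calls$slope,
      Cluster = calls$cluster,
      check.names = FALSE)
    ok <- tryCatch({
      utils::write.csv(format(out, digits = 15, scientific = FALSE, trim = TRUE),
                       path, row.names = FALSE, quote = TRUE)
      TRUE
    }, error = function(e) FALSE)
  }
  assert_that(ok, "could not write '", path, "'", class = "pupsyntax_io_error")
  invisible(path)
}

#' Merge detections separated by less than a minimum gap
#'
#' The shortest meaningful inter-call interval is 10 ms: detections closer
#' than that (including overlaps) are treated as fragments of one
#' vocalization and merged into a single call spanning the union of their
#' time spans, with the band taken as the union of the per-fragment bands
#' (max high frequency, min low frequency, reconstructed from peak +/-
#' bandwidth/2) and the peak frequency of the widest-band fragment.
#' Contour-derived slope is invalidated by merging and reset to `NA`.
#'
#' @param calls A call table.
#' @param gap_ms Minimum gap, ms; gaps strictly below it trigger a merge.
#'   `NULL` disables merging.
#' @return A merged call table.
#' @export
merge_close_calls <- function(calls, gap_ms = 10) {
  if (is.null(gap_ms) || nrow(calls) < 2L) return(calls)
  gaps_ms <- (calls$onset[-1L] - calls$offset[-nrow(calls)]) * 1000
  grp <- cumsum(c(0L, as.integer(gaps_ms >= gap_ms)))
  if (length(unique(grp)) == nrow(calls)) return(calls)
  pieces <- split(seq_len(nrow(calls)), grp)
  merged <- lapply(pieces, function(ix) {
    if (length(ix) == 1L) return(calls[ix, , drop = FALSE])
    sub <- calls[ix, , drop = FALSE]
    lo <- min(sub$peak_frequency - sub$bandwidth / 2)
    hi <- max(sub$peak_frequency + sub$bandwidth / 2)
    widest <- which.max(sub$bandwidth)
    tibble::tibble(
      onset = min(sub$onset), offset = max(sub$offset),
      duration = (max(sub$offset) - min(sub$onset)) * 1000,
      peak_frequency = sub$peak_frequency[widest],
      bandwidth = hi - lo,
      slope = NA_real_, cluster = NA_integer_,
      source_id = paste(sub$source_id, collapse = "+"),
      peak_approximate = any(sub$peak_approximate))
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$onset), , drop = FALSE]
  class(out) <- c("usv_calls", class(tibble::tibble()))
  out
}

#' Load a cohort from a manifest
#'
#' The manifest (CSV, or YAML with a top-level `recordings` list) lists one
#' entry per recording with fields `subject_id`, `litter_id`, `sex`,
#' `group`, `pnd`, `phase`, `duration_s`, `calltable_path`, and optionally
#' `dialect` (`"raven"` default, or `"csv"`).  Paths are resolved relative
#' to the manifest.  The 10 ms merge rule is applied at load; pass
#' `merge_gap_ms = NULL` to disable.
#'
#' @param manifest_path Path to the manifest file.
#' @param merge_gap_ms Merge threshold forwarded to [merge_close_calls()].
#' @param label Cohort label (defaults to the manifest file name).
#' @return A [cohort()].
#' @export
load_cohort <- function(manifest_path, merge_gap_ms = 10, label = NULL) {
  assert_that(file.exists(manifest_path), "manifest not found: ", manifest_path,
              class = "pupsyntax_io_error")
  if (grepl("\\.ya?ml$", manifest_path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(manifest_path)
    entries <- y$recordings %||% y
    man <- do.call(rbind, lapply(entries, function(e) as.data.frame(e, stringsAsFactors = FALSE)))
  } else {
    # read everything as character ("F" would otherwise parse as FALSE)
    man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                           colClasses = "character")
    if (!is.null(man$pnd)) man$pnd <- as.integer(man$pnd)
    if (!is.null(man$duration_s)) man$duration_s <- as.numeric(man$duration_s)
  }
  need <- c("subject_id", "litter_id", "sex", "group", "pnd", "phase",
            "duration_s", "calltable_path")
  missing <- setdiff(need, names(man))
  assert_that(length(missing) == 0L, "manifest missing column(s): ",
              paste(missing, collapse = ", "), class = "pupsyntax_format_error")
  base_dir <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    p <- row$calltable_path
    if (!file.exists(p)) p <- file.path(base_dir, row$calltable_path)
    assert_that(file.exists(p), "call table not found: ", row$calltable_path,
                class = "pupsyntax_io_error")
    meta <- list(subject_id = row$subject_id, litter_id = row$litter_id,
                 sex = row$sex, group = row$group, phase = row$phase,
                 pnd = row$pnd, duration = row$duration_s)
    dialect <- if ("dialect" %in% names(man)) row$dialect else "raven"
    rec <- if (identical(dialect, "csv")) {
      read_deepsqueak_csv(p, meta)
    } else {
      read_raven_selection_table(p, meta)
    }
    rec$calls <- merge_close_calls(rec$calls, merge_gap_ms)
    rec
  })
  co <- cohort(recs, label = label %||% basename(manifest_path))
  s <- summarize_cohort(co)
  for (i in seq_len(nrow(s$by_group_sex))) {
    message(sprintf("cohort %s | group %s sex %s: %d recordings, %d calls",
                    co$label, s$by_group_sex$group[i], s$by_group_sex$sex[i],
                    s$by_group_sex$n_recordings[i], s$by_group_sex$n_calls[i]))
  }
  co
}
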