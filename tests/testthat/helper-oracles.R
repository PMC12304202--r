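# Independent oracles and fixture builders used across test files.
# These re-derive results by the most literal route possible (per-call
# loops, explicit if-else) so they stay independent of the package's
# vectorised implementations.

# Brute-force segmenter: one explicit pass over calls.
brute_segment <- function(onset, offset, seq_gap_ms = 150, bout_gap_ms = 2000) {
  n <- length(onset)
  call_seq <- integer(n)
  call_bout <- integer(n)
  if (n == 0L) return(list(call_sequence = call_seq, call_bout = call_bout))
  s <- 1L; b <- 1L
  call_seq[1L] <- s; call_bout[1L] <- b
  for (i in 2:n) {
    if (n < 2L) break
    gap <- (onset[i] - offset[i - 1L]) * 1000
    # closed lower bounds with the same 1e-9 ms floating-point guard
    if (gap >= bout_gap_ms - 1e-9) {
      b <- b + 1L
      s <- s + 1L
    } else if (gap >= seq_gap_ms - 1e-9) {
      s <- s + 1L
    }
    call_seq[i] <- s
    call_bout[i] <- b
  }
  list(call_sequence = call_seq, call_bout = call_bout)
}

# Random call train with gaps log-uniform over [lo_ms, hi_ms].
random_train <- function(n, lo_ms = 1, hi_ms = 10000, extra_gaps = NULL) {
  dur <- stats::runif(n, 0.02, 0.1)
  gaps <- exp(stats::runif(n - 1, log(lo_ms), log(hi_ms))) / 1000
  if (!is.null(extra_gaps) && n > 2) {
    ix <- sample(n - 1, min(length(extra_gaps), n - 1))
    gaps[ix] <- extra_gaps[seq_along(ix)] / 1000
  }
  onset <- cumsum(c(1, dur[-n] + gaps))
  list(onset = onset, offset = onset + dur)
}

# Column sums of retained conditional probabilities, by explicit loops.
brute_column_sums <- function(model) {
  k <- length(model$labels)
  out <- numeric(k)
  for (j in seq_len(k)) {
    acc <- 0
    for (i in seq_len(k)) {
      if (model$retained[i, j]) acc <- acc + model$cond_prob[i, j]
    }
    out[j] <- acc
  }
  out
}

# Build a recording with given cluster labels and inter-call gaps (ms).
labeled_recording <- function(labels, gaps_ms, dur_ms = 50, subject = "S1",
                              group = "VEH", litter = "L1") {
  n <- length(labels)
  dur <- rep_len(dur_ms, n) / 1000
  onset <- cumsum(c(1, dur[-n] + gaps_ms / 1000))
  calls <- call_table(onset = onset, offset = onset + dur,
                      peak_frequency = 38, bandwidth = 3, slope = 5,
                      cluster = labels,
                      source_id = as.character(seq_len(n)))
  recording(calls, subject_id = subject, litter_id = litter, sex = "F",
            group = group, phase = "DEV6",
            duration = max(onset + dur) + 10)
}

# Uniform sample from a rule's archetype box.
sample_box <- function(rule, n) {
  data.frame(
    peak_frequency = stats::runif(n, rule$box$peak_frequency[1], rule$box$peak_frequency[2]),
    duration = stats::runif(n, rule$box$duration[1], rule$box$duration[2]),
    bandwidth = stats::runif(n, rule$box$bandwidth[1], rule$box$bandwidth[2]),
    slope = stats::runif(n, rule$box$slope[1], rule$box$slope[2]))
}
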