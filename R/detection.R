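# Spectral-entropy call detection.
#
# The detector mirrors the classic bioacoustics workflow: short-time
# Fourier transform with a Hann window (FFT length 512, 75% overlap, frame
# length equal to FFT length, i.e. no zero padding), per-frame Shannon
# entropy of the band-limited normalised power spectrum, and runs of
# low-entropy / high-power frames as call candidates.  Tonal calls
# concentrate power in few bins (entropy near 0); broadband noise spreads
# it (entropy near 1).

#' Spectrogram parameters
#'
#' @param sample_rate Sampling rate, Hz.
#' @param fft_length FFT length in samples (power of two; default 512).
#'   Frame length equals FFT length (no zero padding).
#' @param overlap_fraction Window overlap in `[0, 1)`; default 0.75 so the
#'   hop is `fft_length / 4`.
#' @param band_low,band_high Analysis band, kHz; defaults 40-130 kHz, the
#'   band in which rat pups emit isolation calls.  The upper edge is capped
#'   at Nyquist.
#' @return A list of class `spectrogram_params`.
#' @export
spectrogram_params <- function(sample_rate, fft_length = 512L,
                               overlap_fraction = 0.75,
                               band_low = 40, band_high = 130) {
  assert_that(is_number(sample_rate) && sample_rate > 0, "sample_rate must be positive")
  assert_that(fft_length >= 2 && bitwAnd(as.integer(fft_length), as.integer(fft_length) - 1L) == 0L,
              "fft_length must be a power of two")
  assert_that(overlap_fraction >= 0 && overlap_fraction < 1,
              "overlap_fraction must be in [0, 1)")
  nyq_khz <- sample_rate / 2000
  band_high <- min(band_high, nyq_khz)
  assert_that(band_low < band_high, "band_low must be below band_high (after Nyquist cap)")
  structure(list(sample_rate = sample_rate, fft_length = as.integer(fft_length),
                 overlap_fraction = overlap_fraction,
                 band_low = band_low, band_high = band_high,
                 hop = as.integer(round(fft_length * (1 - overlap_fraction)))),
            class = "spectrogram_params")
}

#' Compute a magnitude-squared spectrogram
#'
#' One-sided STFT power: `frames x bins` matrix of `|X_k|^2` for Hann
#' windowed frames, with `floor((N - fft_length)/hop) + 1` frames and
#' `fft_length/2 + 1` bins.  Times are frame centers (s); frequencies are
#' bin centers (kHz).
#'
#' @param waveform Numeric vector of samples.
#' @param params A [spectrogram_params()].
#' @return A list of class `usv_spectrogram` with `times`, `freqs`,
#'   `power`, and the originating `params`.
#' @export
compute_spectrogram <- function(waveform, params) {
  assert_that(inherits(params, "spectrogram_params"), "params must be spectrogram_params")
  L <- params$fft_length
  hop <- params$hop
  N <- length(waveform)
  assert_that(all(is.finite(waveform)), "waveform contains non-finite samples")
  assert_that(N >= L, "waveform shorter than one frame (", L, " samples)")
  n_frames <- (N - L) %/% hop + 1L
  win <- hann_window(L)
  nb <- L %/% 2L + 1L
  power <- matrix(0, nrow = n_frames, ncol = nb)
  starts <- (seq_len(n_frames) - 1L) * hop
  chunk <- 4096L
  for (i0 in seq(1L, n_frames, by = chunk)) {
    ix <- i0:min(i0 + chunk - 1L, n_frames)
    seg <- matrix(waveform[outer(seq_len(L), starts[ix], `+`)], nrow = L)
    sp <- stats::mvfft(seg * win)
    power[ix, ] <- t(Mod(sp[seq_len(nb), , drop = FALSE])^2)
  }
  structure(list(
    times = (starts + L / 2) / params$sample_rate,
    freqs = (seq_len(nb) - 1L) * params$sample_rate / L / 1000,
    power = power,
    params = params), class = "usv_spectrogram")
}

.band_bins <- function(spec, band) {
  which(spec$freqs >= band[1] & spec$freqs <= band[2])
}

#' Per-frame normalized spectral entropy
#'
#' Shannon entropy of the band-limited power spectrum normalised to a
#' probability vector, divided by `log(K)` for `K` band bins, so values lie
#' in `[0, 1]`: 1 for uniform power across the band, 0 for power in a
#' single bin.  Frames with zero band power are assigned entropy 1
#' (maximally uninformative).
#'
#' @param spec A [compute_spectrogram()] result.
#' @param band Length-2 numeric, kHz; defaults to the band in
#'   `spec$params`.
#' @return Numeric vector, one entropy per frame.
#' @export
frame_entropy <- function(spec, band = NULL) {
  band <- band %||% c(spec$params$band_low, spec$params$band_high)
  bins <- .band_bins(spec, band)
  assert_that(length(bins) >= 2L, "analysis band must contain at least 2 bins")
  p <- spec$power[, bins, drop = FALSE]
  tot <- rowSums(p)
  pn <- p / ifelse(tot > 0, tot, 1)
  plogp <- pn * log(pn)
  plogp[!is.finite(plogp)] <- 0
  h <- -rowSums(plogp) / log(length(bins))
  h[tot <= 0] <- 1
  pmin(pmax(h, 0), 1)
}

#' Detection parameters
#'
#' @param entropy_threshold Frames with normalized entropy strictly below
#'   this are call candidates; default 0.85.
#' @param min_duration_ms Candidate runs shorter than this are dropped;
#'   default 5 ms.
#' @param merge_gap_ms Runs separated by less than this are merged;
#'   default 10 ms, consistent with the I/O merge rule.
#' @param power_floor_db Frames must also exceed the median band power by
#'   this many dB; default 10 dB.  Guards against low-entropy silence.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(entropy_threshold = 0.85, min_duration_ms = 5,
                             merge_gap_ms = 10, power_floor_db = 10) {
  assert_that(entropy_threshold > 0 && entropy_threshold < 1,
              "entropy_threshold must be in (0, 1)")
  structure(list(entropy_threshold = entropy_threshold,
                 min_duration_ms = min_duration_ms,
                 merge_gap_ms = merge_gap_ms,
                 power_floor_db = power_floor_db),
            class = "detection_params")
}

#' Detect calls on a spectrogram
#'
#' Maximal runs of frames with entropy below the threshold *and* band power
#' above the noise floor (median band power + `power_floor_db`), with runs
#' separated by less than `merge_gap_ms` merged and runs shorter than
#' `min_duration_ms` dropped.  Call boundaries are placed half a hop
#' outside the first/last detected frame center.  Each call carries its
#' frequency contour (per-frame argmax frequency in the band, with the
#' corresponding power), from which [contour_features()] derives
#' duration, peak frequency, bandwidth and slope.
#'
#' @param spec A [compute_spectrogram()] result.
#' @param dp A [detection_params()].
#' @return A list of class `usv_detections` with `calls` (tibble: onset,
#'   offset, duration, peak_frequency, bandwidth, slope) and `contours`
#'   (list of per-call tibbles `frame_time`, `peak_freq`, `amplitude`).
#'   Zero detections is a valid result.
#' @export
detect_calls <- function(spec, dp = detection_params()) {
  band <- c(spec$params$band_low, spec$params$band_high)
  bins <- .band_bins(spec, band)
  ent <- frame_entropy(spec, band)
  bp <- rowSums(spec$power[, bins, drop = FALSE])
  floor_lin <- stats::median(bp) * 10^(dp$power_floor_db / 10)
  mask <- ent < dp$entropy_threshold & bp > floor_lin

  hop_s <- spec$params$hop / spec$params$sample_rate
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  empty <- structure(list(
    calls = tibble::tibble(onset = numeric(), offset = numeric(),
                           duration = numeric(), peak_frequency = numeric(),
                           bandwidth = numeric(), slope = numeric()),
    contours = list()), class = "usv_detections")
  if (is.null(dim(runs)) || nrow(runs) == 0L) return(empty)

  # merge runs separated by fewer than merge_gap frames
  gap_frames <- max(1L, as.integer(round(dp$merge_gap_ms / 1000 / hop_s)))
  merged <- list(runs[1L, ])
  if (nrow(runs) > 1L) {
    for (i in 2L:nrow(runs)) {
      prev <- merged[[length(merged)]]
      if (runs[i, 1L] - prev[2L] - 1L < gap_frames) {
        merged[[length(merged)]] <- c(prev[1L], runs[i, 2L])
      } else {
        merged[[length(merged) + 1L]] <- runs[i, ]
      }
    }
  }
  runs <- do.call(rbind, merged)
  dur_ms <- (runs[, 2L] - runs[, 1L] + 1L) * hop_s * 1000
  runs <- runs[dur_ms >= dp$min_duration_ms, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)

  contours <- lapply(seq_len(nrow(runs)), function(i) {
    fr <- runs[i, 1L]:runs[i, 2L]
    sub <- spec$power[fr, bins, drop = FALSE]
    amax <- max.col(sub, ties.method = "first")
    tibble::tibble(frame_time = spec$times[fr],
                   peak_freq = spec$freqs[bins][amax],
                   amplitude = sub[cbind(seq_along(fr), amax)])
  })
  feats <- do.call(rbind, lapply(contours, function(ct) {
    as.data.frame(contour_features(ct, hop_s = hop_s))
  }))
  calls <- tibble::tibble(
    onset = spec$times[runs[, 1L]] - hop_s / 2,
    offset = spec$times[runs[, 2L]] + hop_s / 2,
    duration = feats$duration,
    peak_frequency = feats$peak_frequency,
    bandwidth = feats$bandwidth,
    slope = feats$slope)
  structure(list(calls = calls, contours = contours), class = "usv_detections")
}

#' Acoustic features from a frequency contour
#'
#' Given a call contour (per-frame time, argmax frequency, amplitude):
#' duration is the frame-center span plus one hop (ms); peak frequency is
#' the contour frequency at the maximum-amplitude frame (kHz); bandwidth is
#' the contour's max minus min frequency (kHz); slope is the least-squares
#' line through `(frame_time, peak_freq)` in kHz/s (0 for single-frame
#' contours).
#'
#' @param contour Tibble/data frame with `frame_time` (s), `peak_freq`
#'   (kHz), `amplitude` (linear power).
#' @param hop_s Hop length in seconds (used for the duration of the
#'   one-frame span).
#' @return Named list `duration` (ms), `peak_frequency` (kHz),
#'   `bandwidth` (kHz), `slope` (kHz/s).
#' @export
contour_features <- function(contour, hop_s) {
  n <- nrow(contour)
  assert_that(n >= 1L, "contour must have at least one frame")
  dur_ms <- (if (n > 1L) contour$frame_time[n] - contour$frame_time[1L] else 0) * 1000 +
    hop_s * 1000
  peak <- contour$peak_freq[which.max(contour$amplitude)]
  bw <- max(contour$peak_freq) - min(contour$peak_freq)
  slope <- if (n > 1L) {
    t <- contour$frame_time - mean(contour$frame_time)
    sum(t * (contour$peak_freq - mean(contour$peak_freq))) / sum(t * t)
  } else 0
  list(duration = dur_ms, peak_frequency = peak, bandwidth = bw, slope = slope)
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching by temporal overlap: each true call is
#' matched to the unmatched detection with the largest overlap (zero
#' overlap never matches).  Precision/recall/F1 plus mean absolute
#' onset/offset error in hops over matched pairs.
#'
#' @param truth Tibble with `onset`, `offset` (s).
#' @param detected Tibble with `onset`, `offset` (s).
#' @param hop_s Hop length, seconds.
#' @return List `f1`, `precision`, `recall`, `mean_boundary_error_hops`,
#'   `n_matched`.
#' @export
evaluate_detections <- function(truth, detected, hop_s) {
  nt <- nrow(truth); nd <- nrow(detected)
  if (nt == 0L || nd == 0L) {
    return(list(f1 = if (nt == 0L && nd == 0L) 1 else 0,
                precision = if (nd == 0L) 1 else 0,
                recall = if (nt == 0L) 1 else 0,
                mean_boundary_error_hops = NA_real_, n_matched = 0L))
  }
  used <- rep(FALSE, nd)
  errs <- c()
  matched <- 0L
  for (i in order(truth$onset)) {
    ov <- pmin(truth$offset[i], detected$offset) - pmax(truth$onset[i], detected$onset)
    ov[used] <- -Inf
    j <- which.max(ov)
    if (ov[j] > 0) {
      used[j] <- TRUE
      matched <- matched + 1L
      errs <- c(errs, abs(truth$onset[i] - detected$onset[j]) / hop_s,
                abs(truth$offset[i] - detected$offset[j]) / hop_s)
    }
  }
  precision <- matched / nd
  recall <- matched / nt
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, precision = precision, recall = recall,
       mean_boundary_error_hops = if (length(errs)) mean(errs) else NA_real_,
       n_matched = matched)
}
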