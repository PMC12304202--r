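# Seeded synthetic cohorts.
#
# The generator emulates the data structure the analysis assumes: per
# subject-session a hierarchical call train (bouts > sequences > calls)
# whose gaps are drawn from distributions truncated to their interval
# class, so the generated train segments back to its generative structure
# by construction; cluster labels from a within-bout Markov chain that
# restarts at bout boundaries; per-call features from cluster archetype
# boxes; and group effects (treatment directions reported for the MAM
# model: fewer calls, longer duration, lower peak frequency, narrower
# bandwidth, longer inter-call intervals, later onset, excess flat-call
# transitions, absent potentiation) applied multiplicatively or
# additively.  Effect magnitudes are synthetic design parameters chosen to
# be detectable at realistic cell sizes; they are not published estimates.

#' Group-effect parameters
#'
#' Multipliers and shifts applied to the treated (MAM) group relative to
#' the control.  Defaults encode the reported directions at magnitudes
#' chosen (by a design power analysis) to be detectable at 16 subjects per
#' group; `null_effects()` switches every effect off for type-I
#' calibration.
#'
#' @param call_count_multiplier Multiplier on expected calls (applied as
#'   its square root to sequences/bout and calls/sequence).
#' @param duration_multiplier Multiplier on call duration.
#' @param peak_shift_khz Additive shift on peak frequency, kHz.
#' @param bandwidth_multiplier Multiplier on bandwidth.
#' @param ici_multiplier Multiplier on within- and between-sequence gaps
#'   (gaps stay clamped to their interval class).
#' @param latency_shift_ms Additive shift on first-call latency, ms.
#' @param cluster7_transition_excess Probability mass added to every row's
#'   transition into cluster 7 (other targets rescaled).
#' @param potentiation_multiplier_iso2 Named numeric `c(VEH = , MAM = )`:
#'   multiplier on calls/sequence in the second isolation.
#' @return A list of class `group_effects`.
#' @export
group_effects <- function(call_count_multiplier = 0.5,
                          duration_multiplier = 1.3,
                          peak_shift_khz = -5,
                          bandwidth_multiplier = 0.75,
                          ici_multiplier = 1.5,
                          latency_shift_ms = 6000,
                          cluster7_transition_excess = 0.2,
                          potentiation_multiplier_iso2 = c(VEH = 1.6, MAM = 1.0)) {
  assert_that(call_count_multiplier > 0 && duration_multiplier > 0 &&
                bandwidth_multiplier > 0 && ici_multiplier > 0,
              "multipliers must be positive")
  structure(list(call_count_multiplier = call_count_multiplier,
                 duration_multiplier = duration_multiplier,
                 peak_shift_khz = peak_shift_khz,
                 bandwidth_multiplier = bandwidth_multiplier,
                 ici_multiplier = ici_multiplier,
                 latency_shift_ms = latency_shift_ms,
                 cluster7_transition_excess = cluster7_transition_excess,
                 potentiation_multiplier_iso2 = potentiation_multiplier_iso2),
            class = "group_effects")
}

#' @rdname group_effects
#' @export
null_effects <- function() {
  group_effects(call_count_multiplier = 1, duration_multiplier = 1,
                peak_shift_khz = 0, bandwidth_multiplier = 1,
                ici_multiplier = 1, latency_shift_ms = 0,
                cluster7_transition_excess = 0,
                potentiation_multiplier_iso2 = c(VEH = 1, MAM = 1))
}

# Per-phase timing defaults.  Rates follow the developmental pattern:
# bouts decrease and sequences/bout and calls/sequence increase with age,
# so total output rises toward the oldest day.
.default_timing <- function() {
  mk <- function(bout_rate, spb, cps) {
    list(bout_rate_per_min = bout_rate,
         sequences_per_bout_mean = spb,
         calls_per_sequence_mean = cps,
         within_gap_lnorm = c(meanlog = log(45), sdlog = 0.45),
         between_seq_gap_lnorm = c(meanlog = log(500), sdlog = 0.5),
         bout_gap_exp_mean_ms = 1500,   # gap = 2000 + Exp(mean)
         latency_lnorm = c(meanlog = log(10), sdlog = 0.8),  # seconds
         session_s = 300)
  }
  list(DEV6 = mk(3.0, 1.8, 2.5),
       DEV9 = mk(2.4, 2.2, 3.2),
       DEV12 = mk(2.0, 3.0, 4.5),
       ISO1 = mk(2.2, 2.4, 3.4),
       ISO2 = mk(2.2, 2.4, 3.4))
}

# Per-phase cluster mixture weights: flat (7) and low short (8) calls
# dominate on the youngest day and give way to high-pitched short (1) and
# step-down (2-4) and frequency-modulated (6) calls with age.
.default_mixtures <- function() {
  m <- rbind(
    DEV6 = c(0.06, 0.02, 0.005, 0.02, 0.005, 0.01, 0.55, 0.33),
    DEV9 = c(0.14, 0.08, 0.02, 0.06, 0.015, 0.025, 0.42, 0.24),
    DEV12 = c(0.17, 0.11, 0.04, 0.08, 0.02, 0.05, 0.33, 0.20),
    ISO1 = c(0.15, 0.09, 0.03, 0.07, 0.02, 0.04, 0.38, 0.22),
    ISO2 = c(0.15, 0.09, 0.03, 0.07, 0.02, 0.04, 0.38, 0.22))
  colnames(m) <- as.character(1:8)
  m
}

#' Synthetic cohort configuration
#'
#' Bundles every generator parameter: subjects per group x sex cell,
#' litters per group, per-phase timing models and cluster mixtures, the
#' generative within-bout transition structure (a sticky chain:
#' `self_weight * I + (1 - self_weight) * mixture`), archetype feature
#' boxes from the rule set, group effects, between-subject and
#' between-litter dispersion, and the mandatory seed.
#'
#' @param n_per_cell Subjects per group x sex cell (default 8, i.e. 16 per
#'   group).
#' @param litters_per_group Default 4.
#' @param phases Phases to generate (default all of [USV_PHASES]).
#' @param effects A [group_effects()].
#' @param timing Per-phase timing list (see defaults in source).
#' @param mixtures Per-phase 8-column mixture weight matrix.
#' @param self_weight Self-transition stickiness of the label chain
#'   (default 0.3).
#' @param subject_sdlog,litter_sdlog Log-normal dispersion of
#'   subject-level and litter-level call-rate multipliers.
#' @param ruleset Rule set providing the archetype boxes.
#' @param overlap_mode Draw within/between-sequence gaps *untruncated*
#'   (default `FALSE`): a stress mode in which gaps can straddle the class
#'   thresholds, so the recorded generative partition is no longer
#'   guaranteed to be recoverable by segmentation.
#' @param seed Mandatory integer seed.
#' @return A list of class `cohort_config`.
#' @export
default_cohort_config <- function(n_per_cell = 8, litters_per_group = 4,
                                  phases = USV_PHASES,
                                  effects = group_effects(),
                                  timing = .default_timing(),
                                  mixtures = .default_mixtures(),
                                  self_weight = 0.3,
                                  subject_sdlog = 0.2, litter_sdlog = 0.05,
                                  ruleset = default_ruleset(),
                                  overlap_mode = FALSE,
                                  seed = 1) {
  assert_that(is_number(seed), "seed is mandatory and must be a number")
  phases <- match.arg(phases, USV_PHASES, several.ok = TRUE)
  structure(list(n_per_cell = n_per_cell, litters_per_group = litters_per_group,
                 phases = phases, effects = effects, timing = timing,
                 mixtures = mixtures, self_weight = self_weight,
                 subject_sdlog = subject_sdlog, litter_sdlog = litter_sdlog,
                 ruleset = ruleset, overlap_mode = overlap_mode,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Row-stochastic generative transition matrix for one phase/group.
.transition_matrix <- function(mixture, self_weight, cluster7_excess = 0) {
  k <- length(mixture)
  tm <- self_weight * diag(k) + (1 - self_weight) * matrix(mixture, k, k, byrow = TRUE)
  if (cluster7_excess > 0) {
    for (i in seq_len(k)) {
      p7 <- tm[i, 7L]
      add <- min(cluster7_excess, 1 - p7)
      scale <- if (p7 < 1) (1 - p7 - add) / (1 - p7) else 1
      tm[i, ] <- tm[i, ] * scale
      tm[i, 7L] <- p7 + add
    }
  }
  tm / rowSums(tm)
}

.sample_chain <- function(n, init, tm) {
  labs <- integer(n)
  cum_init <- cumsum(init)
  cum_tm <- t(apply(tm, 1L, cumsum))
  labs[1L] <- findInterval(stats::runif(1), cum_init) + 1L
  if (n > 1L) for (i in 2L:n) {
    labs[i] <- findInterval(stats::runif(1), cum_tm[labs[i - 1L], ]) + 1L
  }
  labs
}

# Sample features for a vector of cluster labels from the archetype boxes:
# truncated normal centered in each box with sd = width/6.
.sample_features <- function(labels, ruleset, features = .features) {
  n <- length(labels)
  out <- matrix(NA_real_, n, length(features), dimnames = list(NULL, features))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    box <- ruleset$rules[[cl]]$box
    for (f in features) {
      b <- box[[f]]
      out[ix, f] <- rtruncnorm(length(ix), mean = mean(b), sd = diff(b) / 6,
                               lo = b[1], hi = b[2])
    }
  }
  out
}

.check_feasible <- function(tm1, effects_applied) {
  exp_calls <- tm1$bout_rate_per_min * tm1$session_s / 60 *
    tm1$sequences_per_bout_mean * tm1$calls_per_sequence_mean
  exp_busy <- exp_calls * (0.15 + 0.1) +
    tm1$bout_rate_per_min * tm1$session_s / 60 * 4
  assert_that(exp_busy < tm1$session_s,
              "infeasible timing config: expected call/gap time (",
              round(exp_busy), " s) exceeds the session (", tm1$session_s, " s)")
}

# Generate one recording's call train; returns calls + ground truth.
# Vectorised: all gaps and durations for the train are drawn in one pass
# and the timeline assembled by cumulative sums.
.generate_recording <- function(phase, group, tm1, mixture, tmat, ruleset,
                                effects, rate_mult, iso2_mult,
                                overlap_mode = FALSE) {
  is_mam <- group == "MAM"
  mc <- if (is_mam) sqrt(effects$call_count_multiplier) else 1
  ici_m <- if (is_mam) effects$ici_multiplier else 1
  spb <- tm1$sequences_per_bout_mean * mc * rate_mult
  cps <- tm1$calls_per_sequence_mean * mc * iso2_mult
  latency_s <- stats::rlnorm(1, tm1$latency_lnorm["meanlog"], tm1$latency_lnorm["sdlog"]) +
    (if (is_mam) effects$latency_shift_ms / 1000 else 0)
  latency_s <- min(latency_s, tm1$session_s / 2)
  n_bouts <- stats::rpois(1, tm1$bout_rate_per_min * tm1$session_s / 60)

  if (n_bouts > 0L) {
    seq_per_bout <- 1L + stats::rpois(n_bouts, max(spb - 1, 0))
    n_seq_total <- sum(seq_per_bout)
    calls_per_seq <- 1L + stats::rpois(n_seq_total, max(cps - 1, 0))
    n_calls <- sum(calls_per_seq)
    seq_id <- rep.int(seq_len(n_seq_total), calls_per_seq)
    seq_bout <- rep.int(seq_len(n_bouts), seq_per_bout)
    bout_id <- seq_bout[seq_id]

    # labels: one Markov chain per bout, restarting at bout boundaries
    labels <- integer(n_calls)
    bout_call_start <- c(1L, cumsum(tabulate(bout_id, n_bouts)) + 1L)
    for (b in seq_len(n_bouts)) {
      ix <- bout_call_start[b]:(bout_call_start[b + 1L] - 1L)
      labels[ix] <- .sample_chain(length(ix), mixture, tmat)
    }
    dur_ms <- .sample_features(labels, ruleset, "duration")[, "duration"] *
      (if (is_mam) effects$duration_multiplier else 1)

    # gap after each call but the last; class determined by the structure
    new_seq <- c(seq_id[-1L] != seq_id[-n_calls], FALSE)
    new_bout <- c(bout_id[-1L] != bout_id[-n_calls], FALSE)
    gaps <- numeric(n_calls)
    n_within <- sum(!new_seq[-n_calls])
    n_bseq <- sum(new_seq & !new_bout)
    if (overlap_mode) {
      # stress mode: untruncated gap draws can straddle the class
      # thresholds, so the generative partition need not be recoverable
      gaps[!new_seq & seq_len(n_calls) < n_calls] <-
        stats::rlnorm(n_within, tm1$within_gap_lnorm["meanlog"],
                      tm1$within_gap_lnorm["sdlog"]) * ici_m
      gaps[new_seq & !new_bout] <-
        stats::rlnorm(n_bseq, tm1$between_seq_gap_lnorm["meanlog"],
                      tm1$between_seq_gap_lnorm["sdlog"]) * ici_m
    } else {
      gaps[!new_seq & seq_len(n_calls) < n_calls] <- pmin(pmax(
        rtrunclnorm(n_within, tm1$within_gap_lnorm["meanlog"],
                    tm1$within_gap_lnorm["sdlog"], 10, 150) * ici_m,
        10), 150 * (1 - 1e-9))
      gaps[new_seq & !new_bout] <- pmin(pmax(
        rtrunclnorm(n_bseq, tm1$between_seq_gap_lnorm["meanlog"],
                    tm1$between_seq_gap_lnorm["sdlog"], 150, 2000) * ici_m,
        150), 2000 * (1 - 1e-9))
    }
    gaps[new_bout] <- 2000 + stats::rexp(sum(new_bout), 1 / tm1$bout_gap_exp_mean_ms)

    onsets <- latency_s + cumsum(c(0, (dur_ms[-n_calls] + gaps[-n_calls]) / 1000))
    offsets <- onsets + dur_ms / 1000
  } else {
    onsets <- offsets <- numeric(0)
    labels <- seq_id <- bout_id <- integer(0)
  }
  if (length(onsets) == 0L) {
    return(list(calls = call_table(), truth = list(labels = integer(),
                                                   call_sequence = integer(),
                                                   call_bout = integer())))
  }
  # features for the full train (per-call, with group effects)
  feats <- .sample_features(labels, ruleset,
                            c("peak_frequency", "bandwidth", "slope"))
  keep <- offsets <= tm1$session_s
  onsets <- onsets[keep]; offsets <- offsets[keep]
  labels <- labels[keep]; seq_id <- seq_id[keep]; bout_id <- bout_id[keep]
  feats <- feats[keep, , drop = FALSE]
  if (length(onsets) == 0L) {
    return(list(calls = call_table(), truth = list(labels = integer(),
                                                   call_sequence = integer(),
                                                   call_bout = integer())))
  }
  peak <- feats[, "peak_frequency"] + (if (is_mam) effects$peak_shift_khz else 0)
  bw <- feats[, "bandwidth"] * (if (is_mam) effects$bandwidth_multiplier else 1)
  slope <- feats[, "slope"]
  calls <- call_table(onset = onsets, offset = offsets,
                      peak_frequency = pmax(peak, 1), bandwidth = pmax(bw, 0),
                      slope = slope, cluster = labels,
                      source_id = as.character(seq_along(onsets)))
  list(calls = calls,
       truth = list(labels = labels,
                    call_sequence = match(seq_id, unique(seq_id)),
                    call_bout = match(bout_id, unique(bout_id))))
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort under `config`: subjects nested in litters nested
#' in groups, each recorded in every requested phase, with a ground-truth
#' sidecar per recording storing the generative cluster labels and
#' sequence/bout partition.  Identical seeds give identical cohorts.
#'
#' Because gap distributions are truncated to their interval class, the
#' temporal segmenter recovers the generative partition exactly; this is a
#' deliberate idealization (see the package vignette).
#'
#' @param config A [default_cohort_config()].
#' @param phases Phases to generate (defaults to `config$phases`).
#' @return A list of class `usv_synth_cohort`: `cohort` (a [cohort()]
#'   whose calls carry the *true* cluster labels), `truth` (named list of
#'   per-recording sidecars, keyed `subject.phase`), `config`.
#' @export
generate_cohort <- function(config, phases = NULL) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  phases <- phases %||% config$phases
  for (ph in phases) .check_feasible(config$timing[[ph]], config$effects)
  withr::with_seed(config$seed, {
    recordings <- list()
    truth <- list()
    for (grp in c("VEH", "MAM")) {
      litter_ids <- paste0(if (grp == "VEH") "V" else "M", seq_len(config$litters_per_group))
      litter_mult <- stats::rlnorm(length(litter_ids), 0, config$litter_sdlog)
      subj_idx <- 0L
      for (sex in c("F", "M")) {
        for (i in seq_len(config$n_per_cell)) {
          subj_idx <- subj_idx + 1L
          lit <- ((subj_idx - 1L) %% config$litters_per_group) + 1L
          sid <- sprintf("%s_%s_%02d", grp, sex, i)
          subj_mult <- stats::rlnorm(1, 0, config$subject_sdlog)
          for (ph in phases) {
            tm1 <- config$timing[[ph]]
            mixture <- config$mixtures[ph, ]
            excess <- if (grp == "MAM") config$effects$cluster7_transition_excess else 0
            tmat <- .transition_matrix(mixture, config$self_weight, excess)
            iso2_mult <- if (ph == "ISO2") {
              unname(config$effects$potentiation_multiplier_iso2[grp])
            } else 1
            g <- .generate_recording(ph, grp, tm1, mixture, tmat,
                                     config$ruleset, config$effects,
                                     rate_mult = litter_mult[lit] * subj_mult,
                                     iso2_mult = iso2_mult,
                                     overlap_mode = isTRUE(config$overlap_mode))
            rec <- recording(g$calls, subject_id = sid,
                             litter_id = litter_ids[lit], sex = sex,
                             group = grp, phase = ph,
                             duration = tm1$session_s)
            key <- paste(sid, ph, sep = ".")
            recordings[[key]] <- rec
            truth[[key]] <- c(g$truth,
                              list(group = grp, phase = ph,
                                   transition_matrix = tmat))
          }
        }
      }
    }
    structure(list(cohort = cohort(unname(recordings), label = "synthetic"),
                   truth = truth, config = config),
              class = "usv_synth_cohort")
  })
}

#' @export
print.usv_synth_cohort <- function(x, ...) {
  cat(sprintf("<usv_synth_cohort> seed %d, %d recordings\n",
              x$config$seed, length(x$cohort$recordings)))
  invisible(x)
}

#' Render a call train as audio
#'
#' Each call becomes a linear frequency sweep (center frequency = peak,
#' extent = slope x duration) with raised-cosine onset/offset ramps,
#' embedded in white Gaussian noise at a target in-band signal-to-noise
#' ratio (call RMS over noise RMS within the analysis band, in dB).
#'
#' @param calls Call table (onset/offset s, peak_frequency kHz, slope
#'   kHz/s); zero calls give pure noise.
#' @param duration_s Session length, seconds.
#' @param fs Sampling rate, Hz (default 250000).
#' @param snr_db In-band SNR, dB (default 20).
#' @param band Analysis band, kHz (default 40-130, capped at `0.45 * fs`).
#' @param ramp_ms Raised-cosine ramp length, ms (default 2).
#' @return List `waveform` (numeric), `fs`, `annotation` (tibble `onset`,
#'   `offset`, `cluster`).
#' @export
synthesize_audio <- function(calls, duration_s, fs = 250000, snr_db = 20,
                             band = c(40, 130), ramp_ms = 2) {
  assert_that(is.finite(snr_db), "snr_db must be finite")
  cap_khz <- 0.45 * fs / 1000
  band[2] <- min(band[2], cap_khz)
  n <- round(duration_s * fs)
  wav <- stats::rnorm(n)
  noise_band_power <- (band[2] - band[1]) * 1000 / (fs / 2)  # sigma^2 = 1
  amp <- sqrt(2 * 10^(snr_db / 10) * noise_band_power)
  for (i in seq_len(nrow(calls))) {
    d <- (calls$offset[i] - calls$onset[i])
    ns <- round(d * fs)
    if (ns < 8L) next
    f0 <- calls$peak_frequency[i] - calls$slope[i] * d / 2
    f1 <- calls$peak_frequency[i] + calls$slope[i] * d / 2
    assert_that(min(f0, f1) > 0 && max(f0, f1) <= cap_khz,
                "call frequencies outside (0, ", round(cap_khz), "] kHz at row ", i)
    finst <- seq(f0, f1, length.out = ns) * 1000
    phase <- 2 * pi * cumsum(finst) / fs
    env <- rep(1, ns)
    nr <- min(round(ramp_ms / 1000 * fs), ns %/% 2)
    if (nr > 0L) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
      env[seq_len(nr)] <- ramp
      env[ns - seq_len(nr) + 1L] <- ramp
    }
    i0 <- round(calls$onset[i] * fs)
    idx <- i0 + seq_len(ns)
    idx <- idx[idx >= 1L & idx <= n]
    wav[idx] <- wav[idx] + amp * sin(phase[seq_along(idx)]) * env[seq_along(idx)]
  }
  ann <- tibble::tibble(onset = calls$onset, offset = calls$offset,
                        cluster = calls$cluster %||% NA_integer_)
  list(waveform = wav, fs = fs, annotation = ann)
}

# -- parameter recovery ------------------------------------------------------

.recording_metrics <- function(rec) {
  ts <- temporal_summary(rec)
  tibble::tibble(subject = rec$subject_id, litter = rec$litter_id,
                 sex = rec$sex, group = rec$group, phase = rec$phase,
                 n_calls = ts$n_calls, mean_duration = mean(rec$calls$duration),
                 mean_peak = mean(rec$calls$peak_frequency),
                 mean_ici = ts$mean_ici_ms)
}

.one_recovery_rep <- function(config, alpha, n_perm_syntax, dev_phase) {
  synth_dev <- generate_cohort(config, phases = dev_phase)
  met <- do.call(rbind, lapply(synth_dev$cohort$recordings, .recording_metrics))
  res <- list()
  for (m in c("n_calls", "mean_duration", "mean_peak", "mean_ici")) {
    gc <- group_contrast(met, metric = m, contrast = c("VEH", "MAM"),
                         exchange = "litter")
    res[[m]] <- tibble::tibble(metric = m, estimate = gc$estimate,
                               p_value = gc$p_value)
  }
  pairs <- collect_transitions(synth_dev$cohort)
  cp <- compare_transition_profiles(pairs, groups = c("VEH", "MAM"),
                                    n_perm = n_perm_syntax,
                                    seed = config$seed)
  res$cluster7 <- tibble::tibble(metric = "cluster7_column_sum",
                                 estimate = unname(cp$column_diff["7"]),
                                 p_value = unname(cp$column_p["7"]))
  cfg_iso <- config
  cfg_iso$seed <- config$seed + 500000000L
  synth_iso <- generate_cohort(cfg_iso, phases = c("ISO1", "ISO2"))
  pot <- potentiation_test(synth_iso$cohort, seed = cfg_iso$seed)
  for (g in c("VEH", "MAM")) {
    row <- pot$per_group[pot$per_group$group == g, ]
    res[[paste0("pot_", g)]] <- tibble::tibble(
      metric = paste0("potentiation_", g),
      estimate = row$mean_delta, p_value = row$p_value)
  }
  do.call(rbind, res)
}

#' Parameter-recovery simulation
#'
#' The acceptance surface for the whole pipeline: over seeded replicates,
#' generates cohorts under `config`, runs the full analysis (per-recording
#' metrics, litter-aware group contrasts, within-bout syntax comparison,
#' paired potentiation test), and tabulates how often each injected effect
#' is detected with the correct sign at level `alpha`.  Under a
#' [null_effects()] config the same detection rates are type-I error
#' rates.
#'
#' @param config A [default_cohort_config()]; its `effects` define the
#'   injected truth.
#' @param n_replicates Number of replicates (default 200).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param alpha Test level (default 0.05).
#' @param n_perm_syntax Permutations in the syntax comparison per
#'   replicate (default 199).
#' @param dev_phase Phase used for the developmental contrasts
#'   (default `"DEV9"`).
#' @return List of class `recovery_report`: `replicates` (tibble `rep`,
#'   `metric`, `estimate`, `p_value`) and `summary` (tibble `metric`,
#'   `expected_sign`, `mean_estimate`, `sign_agreement`,
#'   `detection_rate`), where `detection_rate` counts `p < alpha` with the
#'   expected sign (for `potentiation_MAM` with a null multiplier the
#'   reported rate is the *absence* rate, `p >= alpha`).
#' @export
parameter_recovery <- function(config = default_cohort_config(),
                               n_replicates = 200, seed = 1, alpha = 0.05,
                               n_perm_syntax = 199, dev_phase = "DEV9") {
  rep_seeds <- withr::with_seed(seed, sample.int(10^9, n_replicates))
  reps <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- rep_seeds[r]
    out <- .one_recovery_rep(cfg, alpha, n_perm_syntax, dev_phase)
    out$rep <- r
    out
  })
  replicates <- do.call(rbind, reps)

  ef <- config$effects
  expected <- c(
    n_calls = sign(log(ef$call_count_multiplier)),
    mean_duration = sign(log(ef$duration_multiplier)),
    mean_peak = sign(ef$peak_shift_khz),
    mean_ici = sign(log(ef$ici_multiplier)),
    cluster7_column_sum = sign(ef$cluster7_transition_excess),
    potentiation_VEH = sign(log(ef$potentiation_multiplier_iso2[["VEH"]])),
    potentiation_MAM = sign(log(ef$potentiation_multiplier_iso2[["MAM"]])))
  summary <- do.call(rbind, lapply(names(expected), function(m) {
    sub <- replicates[replicates$metric == m, ]
    es <- expected[[m]]
    if (m == "potentiation_MAM" && es == 0) {
      rate <- mean(sub$p_value >= alpha)     # absence of the effect
      sgn <- NA_real_
    } else if (es == 0) {
      rate <- mean(sub$p_value < alpha)      # type-I rate under a null
      sgn <- NA_real_
    } else {
      rate <- mean(sub$p_value < alpha & sign(sub$estimate) == es)
      sgn <- mean(sign(sub$estimate) == es)
    }
    tibble::tibble(metric = m, expected_sign = es,
                   mean_estimate = mean(sub$estimate),
                   sign_agreement = sgn, detection_rate = rate)
  }))
  structure(list(replicates = replicates, summary = summary,
                 alpha = alpha, n_replicates = n_replicates),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicates, alpha = %.3g\n",
              x$n_replicates, x$alpha))
  print(x$summary)
  invisible(x)
}
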