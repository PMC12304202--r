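# Eight-cluster rule engine.
#
# Calls are assigned to one of eight acoustic clusters by transparent
# interval rules on (peak frequency kHz, duration ms, bandwidth kHz, slope
# kHz/s).  The rule intervals neither partition nor cover feature space,
# so assignment is made total and deterministic by: full 4/4 match wins;
# among several 4/4 matches a fixed priority order (most prevalent call
# types first) wins; with no full match the nearest archetype (smallest
# summed normalized distance to the rule intervals) wins.

# One criterion = a union of intervals; each row (lo, hi, lo_open, hi_open).
.iv <- function(lo, hi, lo_open = FALSE, hi_open = FALSE) {
  cbind(lo = lo, hi = hi, lo_open = as.numeric(lo_open), hi_open = as.numeric(hi_open))
}

.in_iv <- function(x, iv) {
  any(vapply(seq_len(nrow(iv)), function(i) {
    lo_ok <- if (iv[i, "lo_open"] > 0) x > iv[i, "lo"] else x >= iv[i, "lo"]
    hi_ok <- if (iv[i, "hi_open"] > 0) x < iv[i, "hi"] else x <= iv[i, "hi"]
    lo_ok && hi_ok
  }, TRUE))
}

.dist_iv <- function(x, iv) {
  min(vapply(seq_len(nrow(iv)), function(i) {
    if (x < iv[i, "lo"]) iv[i, "lo"] - x
    else if (x > iv[i, "hi"]) x - iv[i, "hi"]
    else 0
  }, 0))
}

# Reference scales for normalized interval distances, one per feature.
FEATURE_SCALES <- c(peak_frequency = 10, duration = 50, bandwidth = 10, slope = 200)

# Half-widths used to widen the taxonomy's approximate ("~") bounds into
# closed intervals: duration ~40 ms -> +/-15, ~150 ms -> +/-50,
# peak ~50 kHz -> +/-5, slope "low, 18" -> +/-18.
APPROX_HALF_WIDTHS <- c(dur40 = 15, dur150 = 50, peak50 = 5, slope18 = 18)

#' The default eight-cluster rule set
#'
#' Interval criteria for the eight call clusters, with open bounds encoded
#' as half-infinite intervals and cluster 1's composite slope criterion as
#' a union of two intervals.  Approximate bounds are widened into closed
#' intervals by the documented half-widths (`APPROX_HALF_WIDTHS` above).
#' The priority order for resolving multiple full matches is
#' 7, 8, 2, 1, 3, 5, 4, 6 (most prevalent call types first); the fallback
#' for calls matching no rule in full is `"NEAREST_ARCHETYPE"`.
#'
#' Each rule also carries a bounded *archetype box* per feature: a
#' sub-region of its intervals that no other cluster matches in full, used
#' by the synthetic generator to sample cluster-typical features and by
#' recovery checks as the rule's interior.
#'
#' @param fallback `"NEAREST_ARCHETYPE"` (default; assignment is total) or
#'   `"UNASSIGNED"` (calls matching no rule in full get `NA`).
#' @return A list of class `usv_ruleset`.
#' @export
default_ruleset <- function(fallback = c("NEAREST_ARCHETYPE", "UNASSIGNED")) {
  fallback <- match.arg(fallback)
  r <- list(
    list(cluster_id = 1L, label = "high-pitched short",
         peak_frequency = .iv(50, Inf, lo_open = TRUE),
         duration = .iv(0, 20, hi_open = TRUE),
         bandwidth = .iv(0, 8, hi_open = TRUE),
         slope = rbind(.iv(35, 82), .iv(440, Inf, lo_open = TRUE)),
         box = list(peak_frequency = c(52, 70), duration = c(8, 18),
                    bandwidth = c(2, 7), slope = c(45, 75))),
    list(cluster_id = 2L, label = "low-pitched long step-down",
         peak_frequency = .iv(0, 41, hi_open = TRUE),
         duration = .iv(100, Inf, lo_open = TRUE),
         bandwidth = .iv(15, 25),
         slope = .iv(-115, -26),
         box = list(peak_frequency = c(33, 40), duration = c(110, 160),
                    bandwidth = c(16, 24), slope = c(-100, -35))),
    list(cluster_id = 3L, label = "medium-pitched short very-wide step-down",
         peak_frequency = .iv(0, 50, hi_open = TRUE),
         duration = .iv(40 - APPROX_HALF_WIDTHS[["dur40"]], 40 + APPROX_HALF_WIDTHS[["dur40"]]),
         bandwidth = .iv(25, Inf, lo_open = TRUE),
         slope = .iv(-Inf, -600, hi_open = TRUE),
         box = list(peak_frequency = c(42, 48), duration = c(30, 50),
                    bandwidth = c(27, 40), slope = c(-900, -650))),
    list(cluster_id = 4L, label = "medium-pitched medium step-down",
         peak_frequency = .iv(0, 50, hi_open = TRUE),
         duration = .iv(50, 150),
         bandwidth = .iv(15, Inf, lo_open = TRUE),
         slope = .iv(-190, -17),
         box = list(peak_frequency = c(42, 48), duration = c(55, 95),
                    bandwidth = c(16, 24), slope = c(-150, -25))),
    list(cluster_id = 5L, label = "step-up",
         peak_frequency = .iv(50 - APPROX_HALF_WIDTHS[["peak50"]], 50 + APPROX_HALF_WIDTHS[["peak50"]]),
         duration = .iv(40 - APPROX_HALF_WIDTHS[["dur40"]], 40 + APPROX_HALF_WIDTHS[["dur40"]]),
         bandwidth = .iv(25, Inf, lo_open = TRUE),
         slope = .iv(400, Inf, lo_open = TRUE),
         box = list(peak_frequency = c(46, 54), duration = c(28, 52),
                    bandwidth = c(27, 40), slope = c(450, 800))),
    list(cluster_id = 6L, label = "frequency-modulated",
         peak_frequency = .iv(0, 50, hi_open = TRUE),
         duration = .iv(150 - APPROX_HALF_WIDTHS[["dur150"]], 150 + APPROX_HALF_WIDTHS[["dur150"]]),
         bandwidth = .iv(8, Inf, lo_open = TRUE),
         slope = .iv(18 - APPROX_HALF_WIDTHS[["slope18"]], 18 + APPROX_HALF_WIDTHS[["slope18"]]),
         box = list(peak_frequency = c(42, 48), duration = c(110, 190),
                    bandwidth = c(10, 14), slope = c(2, 30))),
    list(cluster_id = 7L, label = "low-pitched flat",
         peak_frequency = .iv(0, 40, hi_open = TRUE),
         duration = .iv(75, 155),
         bandwidth = .iv(0, 7, hi_open = TRUE),
         slope = .iv(-35, 125),
         box = list(peak_frequency = c(30, 38), duration = c(85, 145),
                    bandwidth = c(1, 6), slope = c(-20, 60))),
    list(cluster_id = 8L, label = "low-pitched short",
         peak_frequency = .iv(0, 45, hi_open = TRUE),
         duration = .iv(0, 40, hi_open = TRUE),
         bandwidth = .iv(0, 4, hi_open = TRUE),
         slope = .iv(-44, 17),
         box = list(peak_frequency = c(35, 43), duration = c(12, 35),
                    bandwidth = c(0.5, 3.5), slope = c(-30, 10))))
  structure(list(rules = r,
                 priority = c(7L, 8L, 2L, 1L, 3L, 5L, 4L, 6L),
                 fallback = fallback),
            class = "usv_ruleset")
}

.features <- c("peak_frequency", "duration", "bandwidth", "slope")

.check_features <- function(call) {
  for (f in .features) {
    assert_that(!is.null(call[[f]]) && length(call[[f]]) == 1L && is.finite(call[[f]]),
                "call is missing feature '", f, "'")
  }
}

#' Per-cluster match scores for one call
#'
#' For each cluster the score is the number of the four interval criteria
#' satisfied (0-4) minus a fractional penalty in `[0, 1)` derived from the
#' summed normalized distances to the unsatisfied intervals, so clusters
#' with equal criterion counts rank by proximity.
#'
#' @param call Named list or one-row data frame with `peak_frequency`
#'   (kHz), `duration` (ms), `bandwidth` (kHz), `slope` (kHz/s).
#' @param ruleset A [default_ruleset()].
#' @return Tibble with `cluster`, `n_satisfied`, `distance`, `score`.
#' @export
match_scores <- function(call, ruleset = default_ruleset()) {
  .check_features(call)
  rows <- lapply(ruleset$rules, function(rule) {
    sat <- vapply(.features, function(f) .in_iv(call[[f]], rule[[f]]), TRUE)
    dist <- sum(vapply(.features, function(f)
      .dist_iv(call[[f]], rule[[f]]) / FEATURE_SCALES[[f]], 0))
    tibble::tibble(cluster = rule$cluster_id, n_satisfied = sum(sat),
                   distance = dist, score = sum(sat) - dist / (1 + dist))
  })
  do.call(rbind, rows)
}

#' Assign one call to a cluster
#'
#' A unique full (4/4) match wins; among several full matches the rule
#' set's priority order wins; with no full match the fallback policy
#' applies (nearest archetype by summed normalized interval distance, ties
#' broken by priority, or `NA` under the `"UNASSIGNED"` policy).
#'
#' @inheritParams match_scores
#' @return List `cluster` (integer or `NA`), `full_match` (logical),
#'   `low_confidence` (logical: fallback was used).
#' @examples
#' # a long, low-pitched, flat, narrow call: cluster 7
#' assign_cluster(list(peak_frequency = 38, duration = 120,
#'                     bandwidth = 5, slope = 20))$cluster
#' @export
assign_cluster <- function(call, ruleset = default_ruleset()) {
  sc <- match_scores(call, ruleset)
  prio_rank <- match(sc$cluster, ruleset$priority)
  full <- which(sc$n_satisfied == 4L)
  if (length(full) > 0L) {
    win <- full[which.min(prio_rank[full])]
    return(list(cluster = sc$cluster[win], full_match = TRUE, low_confidence = FALSE))
  }
  if (ruleset$fallback == "UNASSIGNED") {
    return(list(cluster = NA_integer_, full_match = FALSE, low_confidence = TRUE))
  }
  ord <- order(sc$distance, prio_rank)
  list(cluster = sc$cluster[ord[1L]], full_match = FALSE, low_confidence = TRUE)
}

#' Classify all calls of a recording or call table
#'
#' @param x A [recording()] or a call table.
#' @param ruleset A [default_ruleset()].
#' @param allow_approximate Classify calls whose peak frequency is flagged
#'   approximate?  Default `FALSE` (they are refused with an error), since
#'   peak frequency enters every cluster rule.
#' @return `x` with the `cluster` column filled in and a logical
#'   `cluster_low_confidence` column added.
#' @export
classify_calls <- function(x, ruleset = default_ruleset(), allow_approximate = FALSE) {
  if (inherits(x, "usv_recording")) {
    x$calls <- classify_calls(x$calls, ruleset, allow_approximate)
    return(x)
  }
  calls <- x
  if (nrow(calls) == 0L) {
    calls$cluster_low_confidence <- logical()
    return(calls)
  }
  if (!allow_approximate && any(calls$peak_approximate %||% FALSE)) {
    stop_ps("refusing to classify ", sum(calls$peak_approximate),
            " call(s) with approximate peak frequency; ",
            "set allow_approximate = TRUE to override")
  }
  res <- lapply(seq_len(nrow(calls)), function(i)
    assign_cluster(calls[i, ], ruleset))
  calls$cluster <- vapply(res, function(r) r$cluster, 1L)
  calls$cluster_low_confidence <- vapply(res, function(r) r$low_confidence, TRUE)
  calls
}

#' Per-cluster proportions
#'
#' Counts and proportions of cluster labels, with the companion
#' variance-stabilising arcsine transform `asin(sqrt(p))` used for
#' proportion contrasts.  Proportions sum to one; zero calls give an empty
#' table (never NaNs).
#'
#' @param x A classified [recording()], [cohort()], call table, or an
#'   integer vector of labels.
#' @return Tibble with `cluster`, `n`, `proportion`, `arcsine`.
#' @export
cluster_distribution <- function(x) {
  labels <- if (inherits(x, "usv_cohort")) {
    unlist(lapply(x$recordings, function(r) r$calls$cluster))
  } else if (inherits(x, "usv_recording")) {
    x$calls$cluster
  } else if (is.data.frame(x)) {
    x$cluster
  } else {
    x
  }
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) {
    return(tibble::tibble(cluster = integer(), n = integer(),
                          proportion = numeric(), arcsine = numeric()))
  }
  tab <- table(labels)
  p <- as.numeric(tab) / length(labels)
  tibble::tibble(cluster = as.integer(names(tab)), n = as.integer(tab),
                 proportion = p, arcsine = asin(sqrt(p)))
}
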