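# Within-bout cluster-transition ("syntax") models.
#
# Transitions are counted over consecutive call pairs inside the same bout
# only; pairs never span a bout boundary.  Rare transition types are
# excluded on *joint* relative frequency (strictly below `min_joint_freq`,
# default 0.01); a separate, display-only threshold (default 0.075) masks
# weak conditional probabilities in flow-path plots.  Column sums of the
# retained conditional probabilities quantify how likely each cluster is
# to be the *next* call; they are sums over source rows, not
# probabilities, and can exceed 1.

#' Collect within-bout transition pairs
#'
#' @param recordings A [cohort()], a list of classified recordings, or a
#'   single recording.
#' @param segmentations Optional list of [segment_calls()] results, one
#'   per recording (computed with `thresholds` when `NULL`).
#' @param thresholds An [interval_thresholds()]; the bout gap must match
#'   the temporal analysis (default 2000 ms).
#' @return Tibble with one row per ordered within-bout pair: `source`,
#'   `target` (cluster labels), `recording` (subject id), `group`.
#' @export
collect_transitions <- function(recordings, segmentations = NULL,
                                thresholds = interval_thresholds()) {
  if (inherits(recordings, "usv_cohort")) recordings <- recordings$recordings
  if (inherits(recordings, "usv_recording")) recordings <- list(recordings)
  out <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    labels <- rec$calls$cluster
    if (length(labels) > 0L && anyNA(labels)) {
      stop_ps("unclassified call(s) in recording '", rec$subject_id, "': rows ",
              paste(utils::head(which(is.na(labels)), 5L), collapse = ", "))
    }
    if (length(labels) < 2L) return(NULL)
    seg <- if (!is.null(segmentations)) segmentations[[i]] else segment_calls(rec, thresholds)
    same_bout <- seg$call_bout[-1L] == seg$call_bout[-length(seg$call_bout)]
    if (!any(same_bout)) return(NULL)
    tibble::tibble(source = labels[-length(labels)][same_bout],
                   target = labels[-1L][same_bout],
                   recording = rec$subject_id,
                   group = rec$group)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    return(tibble::tibble(source = integer(), target = integer(),
                          recording = character(), group = character()))
  }
  do.call(rbind, out)
}

.model_from_counts <- function(counts, min_joint_freq, display_threshold,
                               renormalize = FALSE) {
  total <- sum(counts)
  joint <- if (total > 0) counts / total else counts
  retained <- joint >= min_joint_freq
  rs <- rowSums(counts)
  cond <- counts / ifelse(rs > 0, rs, 1)
  kept_cond <- cond * retained
  if (renormalize) {
    krs <- rowSums(kept_cond)
    kept_cond <- kept_cond / ifelse(krs > 0, krs, 1)
  }
  structure(list(labels = as.integer(rownames(counts)),
                 counts = counts, joint_freq = joint, cond_prob = cond,
                 retained = retained,
                 column_sums = colSums(kept_cond),
                 display_mask = cond >= display_threshold,
                 total_transitions = total,
                 min_joint_freq = min_joint_freq,
                 display_threshold = display_threshold,
                 renormalized = renormalize),
            class = "usv_transition_model")
}

.count_matrix <- function(pairs, labels) {
  k <- length(labels)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  if (nrow(pairs) > 0L) {
    t <- table(factor(pairs$source, levels = labels),
               factor(pairs$target, levels = labels))
    m <- m + unclass(t)
  }
  m
}

#' Build a transition model from pooled pairs
#'
#' @param pairs Pair table from [collect_transitions()].
#' @param min_joint_freq Transition types with joint relative frequency
#'   strictly below this are excluded (default 0.01); exactly at the
#'   threshold is retained.  Set `exclude_on = "conditional"` to apply the
#'   exclusion to conditional probabilities instead.
#' @param display_threshold Conditional probabilities below this are
#'   masked in `display_mask` (plotting only; default 0.075).
#' @param labels Label universe (default: labels present in `pairs`,
#'   sorted).
#' @param renormalize Renormalise each row of retained conditional
#'   probabilities to 1 after exclusion (default `FALSE`: excluded mass is
#'   not redistributed).
#' @param exclude_on `"joint"` (default) or `"conditional"`.
#' @return A list of class `usv_transition_model`: `labels`, `counts`
#'   (source x target, diagonal = repetitive use), `joint_freq`,
#'   `cond_prob` (row-normalised), `retained` mask, `column_sums` (per
#'   target, over retained entries), `display_mask`.
#' @examples
#' pairs <- tibble::tibble(source = c(7L, 7L, 1L), target = c(7L, 1L, 7L),
#'                         recording = "r1", group = "VEH")
#' m <- build_transition_model(pairs)
#' m$cond_prob       # row 7: 0.5 / 0.5; row 1: 1
#' m$column_sums     # 7: 1.5, 1: 0.5
#' column_sum_profile(m)
#' @export
build_transition_model <- function(pairs, min_joint_freq = 0.01,
                                   display_threshold = 0.075, labels = NULL,
                                   renormalize = FALSE,
                                   exclude_on = c("joint", "conditional")) {
  exclude_on <- match.arg(exclude_on)
  labels <- labels %||% sort(unique(c(pairs$source, pairs$target)))
  counts <- .count_matrix(pairs, labels)
  m <- .model_from_counts(counts, min_joint_freq, display_threshold, renormalize)
  if (exclude_on == "conditional") {
    m$retained <- m$cond_prob >= min_joint_freq & m$counts > 0
    kept <- m$cond_prob * m$retained
    if (renormalize) {
      krs <- rowSums(kept)
      kept <- kept / ifelse(krs > 0, krs, 1)
    }
    m$column_sums <- colSums(kept)
  }
  m
}

#' @export
print.usv_transition_model <- function(x, ...) {
  cat(sprintf("<usv_transition_model> %d labels, %d transitions (%d types retained at joint >= %.3g)\n",
              length(x$labels), x$total_transitions, sum(x$retained), x$min_joint_freq))
  invisible(x)
}

#' Next-call column-sum profile
#'
#' For each cluster, the sum over source rows of the retained conditional
#' probabilities of transitioning *to* it, sorted ascending (the order
#' used in stacked next-call plots).  Scores are sums, not probabilities,
#' and can exceed 1.
#'
#' @param model A [build_transition_model()] result.
#' @return Tibble `cluster`, `score`, ascending by score.  Empty for an
#'   empty model.
#' @export
column_sum_profile <- function(model) {
  if (length(model$labels) == 0L || model$total_transitions == 0L) {
    return(tibble::tibble(cluster = integer(), score = numeric()))
  }
  out <- tibble::tibble(cluster = model$labels, score = unname(model$column_sums))
  out[order(out$score, out$cluster), ]
}

#' Compare transition structure between two groups
#'
#' Pools pairs within each group into one transition model, reports
#' per-edge conditional-probability differences and per-column next-call
#' score differences (group2 minus group1), and attaches two-sided
#' permutation p-values obtained by shuffling *recording-level* group
#' labels (recordings, not pairs, are the exchangeable units) with
#' Benjamini-Hochberg control across edges and across columns.
#'
#' @param pairs Pair table from [collect_transitions()] covering both
#'   groups (columns `source`, `target`, `recording`, `group`).
#' @param groups Length-2 character: the two group labels to compare, in
#'   the order `(reference, comparison)`.
#' @param n_perm Number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param min_joint_freq,display_threshold Forwarded to the models.
#' @return List with `model1`, `model2`, `edge_diff` (matrix), `edge_p`,
#'   `edge_p_adj`, `column_diff` (named vector), `column_p`,
#'   `column_p_adj`, `labels`, `n_perm`.
#' @export
compare_transition_profiles <- function(pairs, groups = c("VEH", "MAM"),
                                        n_perm = 999, seed = 1,
                                        min_joint_freq = 0.01,
                                        display_threshold = 0.075) {
  assert_that(length(groups) == 2L, "groups must have length 2")
  pairs <- pairs[pairs$group %in% groups, , drop = FALSE]
  recs <- unique(pairs[, c("recording", "group")])
  n_per <- table(factor(recs$group, levels = groups))
  assert_that(all(n_per >= 2L),
              "need at least 2 recordings per group (got ",
              paste(n_per, collapse = ", "), ")")
  labels <- sort(unique(c(pairs$source, pairs$target)))
  k <- length(labels)

  # per-recording flattened count matrices: (k*k) x n_recordings
  rec_ids <- recs$recording
  cnt <- vapply(rec_ids, function(rid)
    as.vector(.count_matrix(pairs[pairs$recording == rid, , drop = FALSE], labels)),
    numeric(k * k))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, ncol = length(rec_ids))

  stat_fun <- function(is_g2) {
    c1 <- matrix(rowSums(cnt[, !is_g2, drop = FALSE]), k, k, dimnames = list(labels, labels))
    c2 <- matrix(rowSums(cnt[, is_g2, drop = FALSE]), k, k, dimnames = list(labels, labels))
    m1 <- .model_from_counts(c1, min_joint_freq, display_threshold)
    m2 <- .model_from_counts(c2, min_joint_freq, display_threshold)
    list(edge = m2$cond_prob - m1$cond_prob,
         col = m2$column_sums - m1$column_sums,
         m1 = m1, m2 = m2)
  }
  obs_g2 <- recs$group == groups[2L]
  obs <- stat_fun(obs_g2)

  withr::with_seed(seed, {
    edge_ge <- matrix(0, k, k)
    col_ge <- numeric(k)
    for (b in seq_len(n_perm)) {
      perm <- sample(obs_g2)
      st <- stat_fun(perm)
      edge_ge <- edge_ge + (abs(st$edge) >= abs(obs$edge) - 1e-12)
      col_ge <- col_ge + (abs(st$col) >= abs(obs$col) - 1e-12)
    }
  })
  edge_p <- (edge_ge + 1) / (n_perm + 1)
  col_p <- (col_ge + 1) / (n_perm + 1)
  dimnames(edge_p) <- list(labels, labels)
  edge_p_adj <- matrix(stats::p.adjust(edge_p, method = "BH"), k, k,
                       dimnames = list(labels, labels))
  list(model1 = obs$m1, model2 = obs$m2,
       edge_diff = obs$edge, edge_p = edge_p, edge_p_adj = edge_p_adj,
       column_diff = stats::setNames(obs$col, labels),
       column_p = stats::setNames(col_p, labels),
       column_p_adj = stats::setNames(stats::p.adjust(col_p, method = "BH"), labels),
       labels = labels, n_perm = n_perm, groups = groups)
}

#' Export a transition table as CSV
#'
#' Writes the conditional-probability matrix (rows = source cluster,
#' columns = target cluster) in the layout of supplementary transition
#' tables.
#'
#' @param model A [build_transition_model()] result.
#' @param path Output path.
#' @param what `"cond_prob"` (default), `"joint_freq"` or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(model, path, what = c("cond_prob", "joint_freq", "counts")) {
  what <- match.arg(what)
  utils::write.csv(as.data.frame(model[[what]]), path, row.names = TRUE)
  invisible(path)
}

#' Render a transition model as a DOT flow graph
#'
#' Edges are conditional probabilities; edges below the display threshold
#' (or excluded by the joint-frequency rule) are omitted, matching the
#' flow-path convention.
#'
#' @param model A [build_transition_model()] result.
#' @return A character scalar of DOT source.
#' @export
transition_dot <- function(model) {
  lines <- c("digraph syntax {", "  rankdir=LR;")
  k <- length(model$labels)
  for (i in seq_len(k)) {
    lines <- c(lines, sprintf("  c%d [label=\"%d\"];", model$labels[i], model$labels[i]))
  }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (model$retained[i, j] && model$display_mask[i, j]) {
      lines <- c(lines, sprintf("  c%d -> c%d [label=\"%.3f\", penwidth=%.2f];",
                                model$labels[i], model$labels[j],
                                model$cond_prob[i, j],
                                0.5 + 4 * model$cond_prob[i, j]))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
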