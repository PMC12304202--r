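# Group-level designs and permutation contrasts.
#
# Permutation tests stand in for mixed-design ANOVA: for between-group
# contrasts the exchangeable units are litters (pups within a litter are
# correlated), and for the paired potentiation contrast the within-subject
# deltas are sign-flipped.  Exact enumeration is used whenever feasible;
# otherwise Monte Carlo with a mandatory seed.

#' Build a long-format design table from a cohort
#'
#' One row per recording with the design factors and a per-recording
#' metric.  The subject x phase grid is completed: recordings a subject is
#' missing are emitted as flagged-missing rows (never silently imputed).
#' The optional mean-imputation flag replaces a missing value with the
#' mean of the intact values of the same group and phase, mirroring the
#' common handling of technically lost sessions; it is off by default.
#'
#' @param co A [cohort()].
#' @param metric_fun Function `recording -> scalar` (e.g.
#'   `function(r) nrow(r$calls)`).
#' @param metric_name Name for the metric column ("value" by default).
#' @param impute_missing Replace missing cells with the group-phase mean
#'   of intact values?  Default `FALSE`.
#' @return Tibble `subject`, `litter`, `sex`, `group`, `phase`, `pnd`,
#'   `value`, `missing`.
#' @export
build_design <- function(co, metric_fun, metric_name = "value",
                         impute_missing = FALSE) {
  assert_that(inherits(co, "usv_cohort"), "co must be a usv_cohort")
  rows <- lapply(co$recordings, function(r) {
    v <- tryCatch(metric_fun(r), error = function(e) {
      stop_ps("metric failed for subject '", r$subject_id, "', phase ", r$phase,
              ": ", conditionMessage(e))
    })
    tibble::tibble(subject = r$subject_id, litter = r$litter_id, sex = r$sex,
                   group = r$group, phase = r$phase, pnd = r$pnd,
                   value = as.numeric(v), missing = FALSE)
  })
  df <- do.call(rbind, rows)
  phases <- unique(df$phase)
  subj <- unique(df[, c("subject", "litter", "sex", "group")])
  grid <- merge(subj, data.frame(phase = phases), by = NULL)
  miss <- grid[!paste(grid$subject, grid$phase) %in% paste(df$subject, df$phase), , drop = FALSE]
  if (nrow(miss) > 0L) {
    miss$pnd <- vapply(miss$phase, phase_pnd, 1L)
    miss$value <- NA_real_
    miss$missing <- TRUE
    df <- rbind(df, tibble::as_tibble(miss[, names(df)]))
  }
  if (impute_missing && any(df$missing)) {
    for (i in which(df$missing)) {
      intact <- df$value[!df$missing & df$group == df$group[i] & df$phase == df$phase[i]]
      df$value[i] <- mean(intact)
    }
  }
  names(df)[names(df) == "value"] <- metric_name
  df[order(df$subject, df$phase), ]
}

# Exact sign-flip null distribution of sum(delta * s), s in {-1,+1}^n,
# by meet-in-the-middle enumeration (feasible through n = 20).
.signflip_sums <- function(delta) {
  half <- function(v) {
    s <- 0
    for (d in v) s <- as.vector(outer(s, c(-d, d), `+`))
    s
  }
  a <- delta[seq_len(length(delta) %/% 2)]
  b <- delta[-seq_len(length(delta) %/% 2)]
  as.vector(outer(half(a), half(b), `+`))
}

#' Paired sign-flip permutation test
#'
#' Tests whether within-subject deltas are centred at zero by flipping the
#' sign of each delta: exact enumeration of all `2^n` sign patterns when
#' `n <= exact_max_n` (default 20), Monte Carlo otherwise.  The statistic
#' is the sum of deltas; p is the two-sided tail probability.
#'
#' @param delta Numeric vector of within-subject differences.
#' @param n_flips Monte Carlo flips when enumeration is infeasible
#'   (default 10000).
#' @param exact_max_n Enumerate exactly up to this n (default 20).
#' @param seed RNG seed (Monte Carlo only).
#' @return List `p_value`, `estimate` (mean delta), `direction`
#'   (sign of the mean), `method`, `n`.
#' @export
signflip_test <- function(delta, n_flips = 10000, exact_max_n = 20, seed = 1) {
  delta <- delta[is.finite(delta)]
  n <- length(delta)
  assert_that(n >= 1L, "no finite deltas")
  obs <- sum(delta)
  if (n <= exact_max_n) {
    sums <- .signflip_sums(delta)
    p <- mean(abs(sums) >= abs(obs) - 1e-12)
    method <- sprintf("exact (2^%d sign patterns)", n)
  } else {
    withr::with_seed(seed, {
      flips <- matrix(sample(c(-1, 1), n * n_flips, replace = TRUE), nrow = n)
      sums <- colSums(flips * delta)
    })
    p <- (sum(abs(sums) >= abs(obs) - 1e-12) + 1) / (n_flips + 1)
    method <- sprintf("Monte Carlo (%d flips)", n_flips)
  }
  list(p_value = p, estimate = mean(delta), direction = sign(mean(delta)),
       method = method, n = n)
}

#' Maternal potentiation contrast
#'
#' Compares call counts between a first and a second isolation of the same
#' subjects (the second following brief reunion with the dam).  Subjects
#' present in only one phase are excluded with a warning.  Per group, the
#' within-subject deltas (second minus first) are tested with
#' [signflip_test()].
#'
#' @param x A [cohort()] containing `ISO1` and `ISO2` recordings, or a
#'   data frame with columns `subject`, `group`, `n_iso1`, `n_iso2`.
#' @param seed RNG seed for Monte Carlo sign flips.
#' @param ... Passed to [signflip_test()].
#' @return List of class `potentiation_result`: `per_subject` tibble
#'   (`subject`, `group`, `n_iso1`, `n_iso2`, `delta`, `ratio`) and
#'   `per_group` tibble (`group`, `n`, `mean_delta`, `mean_ratio`,
#'   `direction`, `p_value`, `method`).
#' @export
potentiation_test <- function(x, seed = 1, ...) {
  if (inherits(x, "usv_cohort")) {
    iso <- Filter(function(r) r$phase %in% c("ISO1", "ISO2"), x$recordings)
    df <- tibble::tibble(
      subject = vapply(iso, function(r) r$subject_id, ""),
      group = vapply(iso, function(r) r$group, ""),
      phase = vapply(iso, function(r) r$phase, ""),
      n = vapply(iso, function(r) nrow(r$calls), 0L))
    wide <- merge(df[df$phase == "ISO1", c("subject", "group", "n")],
                  df[df$phase == "ISO2", c("subject", "n")],
                  by = "subject", suffixes = c("_iso1", "_iso2"),
                  all = TRUE)
    incomplete <- is.na(wide$n_iso1) | is.na(wide$n_iso2)
    if (any(incomplete)) {
      warn_ps(sum(incomplete), " subject(s) lack one isolation phase; excluded: ",
              paste(utils::head(wide$subject[incomplete], 5L), collapse = ", "))
      wide <- wide[!incomplete, , drop = FALSE]
    }
    x <- wide
  }
  assert_that(all(c("subject", "group", "n_iso1", "n_iso2") %in% names(x)),
              "need columns subject, group, n_iso1, n_iso2")
  per_subject <- tibble::tibble(
    subject = x$subject, group = x$group,
    n_iso1 = x$n_iso1, n_iso2 = x$n_iso2,
    delta = x$n_iso2 - x$n_iso1,
    ratio = x$n_iso2 / pmax(x$n_iso1, 1))
  groups <- sort(unique(per_subject$group))
  per_group <- do.call(rbind, lapply(groups, function(g) {
    d <- per_subject$delta[per_subject$group == g]
    t <- signflip_test(d, seed = seed, ...)
    tibble::tibble(group = g, n = t$n, mean_delta = t$estimate,
                   mean_ratio = mean(per_subject$ratio[per_subject$group == g]),
                   direction = t$direction, p_value = t$p_value,
                   method = t$method)
  }))
  structure(list(per_subject = per_subject, per_group = per_group),
            class = "potentiation_result")
}

#' @export
print.potentiation_result <- function(x, ...) {
  cat("<potentiation_result>\n")
  print(x$per_group)
  invisible(x)
}

#' Between-group permutation contrast with litter-aware shuffling
#'
#' Tests a difference in group means by permuting treatment labels.
#' Litters, not subjects, are the exchangeable units: whole litters are
#' reassigned between groups, preserving litter blocks exactly (a nested
#' litter check).  All litter-to-group assignments are enumerated when
#' there are at most `exact_max` of them; otherwise Monte Carlo.  If a
#' group contains a single litter, litter-aware shuffling is refused and
#' the test falls back to subject-level permutation with a loud warning.
#'
#' @param design Data frame with columns `group`, `litter`, and the metric
#'   column.
#' @param metric Name of the metric column (default `"value"`).
#' @param contrast Length-2 character: the estimate is
#'   `mean(contrast[2]) - mean(contrast[1])`.
#' @param n_perm Monte Carlo permutations (default 9999).
#' @param seed RNG seed.
#' @param exchange `"litter"` (default) or `"subject"`.
#' @param exact_max Enumerate exactly when the number of distinct
#'   assignments is at most this (default 20000).
#' @return List `estimate`, `p_value`, `method`, `n_perm_used`,
#'   `exchange_unit`.
#' @export
group_contrast <- function(design, metric = "value", contrast = c("VEH", "MAM"),
                           n_perm = 9999, seed = 1, exchange = c("litter", "subject"),
                           exact_max = 20000) {
  exchange <- match.arg(exchange)
  df <- design[design$group %in% contrast & is.finite(design[[metric]]), , drop = FALSE]
  n_per <- table(factor(df$group, levels = contrast))
  assert_that(all(n_per >= 2L), "need at least 2 subjects per group")
  y <- df[[metric]]
  g2 <- df$group == contrast[2L]
  obs <- mean(y[g2]) - mean(y[!g2])

  if (exchange == "litter") {
    lit <- unique(df[, c("litter", "group")])
    lit_n <- table(factor(lit$group, levels = contrast))
    if (any(lit_n < 2L)) {
      warn_ps("a group has fewer than 2 litters; falling back to ",
              "subject-level permutation (litter structure NOT respected)")
      exchange <- "subject"
    }
  }

  stat_for <- function(g2_mask) mean(y[g2_mask]) - mean(y[!g2_mask])

  if (exchange == "litter") {
    litters <- unique(df$litter)
    n2 <- sum(unique(df[, c("litter", "group")])$group == contrast[2L])
    n_assign <- choose(length(litters), n2)
    if (n_assign <= exact_max) {
      combos <- utils::combn(litters, n2, simplify = FALSE)
      stats <- vapply(combos, function(s) stat_for(df$litter %in% s), 0)
      p <- mean(abs(stats) >= abs(obs) - 1e-12)
      method <- sprintf("exact litter permutation (%d assignments)", length(combos))
      n_used <- length(combos)
    } else {
      withr::with_seed(seed, {
        stats <- vapply(seq_len(n_perm), function(b) {
          s <- sample(litters, n2)
          stat_for(df$litter %in% s)
        }, 0)
      })
      p <- (sum(abs(stats) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
      method <- sprintf("Monte Carlo litter permutation (%d)", n_perm)
      n_used <- n_perm
    }
  } else {
    withr::with_seed(seed, {
      stats <- vapply(seq_len(n_perm), function(b) stat_for(sample(g2)), 0)
    })
    p <- (sum(abs(stats) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
    method <- sprintf("Monte Carlo subject permutation (%d)", n_perm)
    n_used <- n_perm
  }
  list(estimate = obs, p_value = p, method = method, n_perm_used = n_used,
       exchange_unit = exchange)
}

#' Per-cluster proportion contrast with arcsine transform
#'
#' Applies the variance-stabilising transform `y = asin(sqrt(p))` to each
#' subject's per-cluster proportion, then contrasts groups per cluster
#' with [group_contrast()], reporting raw and transformed effects and
#' Benjamini-Hochberg adjusted p-values across clusters.
#'
#' @param design Data frame with columns `subject`, `litter`, `group`,
#'   `cluster`, `proportion` (in `[0, 1]`).
#' @param contrast,n_perm,seed,exchange Passed to [group_contrast()].
#' @return Tibble `cluster`, `effect_raw`, `effect_arcsine`, `p_value`,
#'   `p_adj`.
#' @export
cluster_proportion_contrast <- function(design, contrast = c("VEH", "MAM"),
                                        n_perm = 9999, seed = 1,
                                        exchange = "litter") {
  assert_that(all(design$proportion >= 0 & design$proportion <= 1, na.rm = TRUE),
              "proportions must lie in [0, 1]",
              class = "pupsyntax_validation_error")
  design$arcsine <- asin(sqrt(design$proportion))
  clusters <- sort(unique(design$cluster))
  rows <- lapply(clusters, function(cl) {
    sub <- design[design$cluster == cl, , drop = FALSE]
    raw <- group_contrast(sub, metric = "proportion", contrast = contrast,
                          n_perm = n_perm, seed = seed, exchange = exchange)
    tr <- group_contrast(sub, metric = "arcsine", contrast = contrast,
                         n_perm = n_perm, seed = seed, exchange = exchange)
    tibble::tibble(cluster = cl, effect_raw = raw$estimate,
                   effect_arcsine = tr$estimate, p_value = tr$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
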