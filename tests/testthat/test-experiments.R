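# Design tables, sign-flip and litter-aware permutation tests.

small_cohort <- function(seed = 1, phases = c("DEV6", "DEV9", "DEV12")) {
  cfg <- default_cohort_config(n_per_cell = 2, litters_per_group = 2,
                               seed = seed)
  generate_cohort(cfg, phases = phases)$cohort
}

test_that("design tables complete the subject-phase grid and flag missing cells", {
  co <- small_cohort()
  full <- build_design(co, function(r) nrow(r$calls), "n_calls")
  expect_equal(nrow(full), 8 * 3)  # 8 subjects x 3 phases
  expect_false(any(full$missing))

  co_miss <- cohort(co$recordings[-2], label = "missing-one")
  d <- build_design(co_miss, function(r) nrow(r$calls), "n_calls")
  expect_equal(nrow(d), 24L)
  expect_equal(sum(d$missing), 1L)
  expect_true(is.na(d$n_calls[d$missing]))

  # imputation fills exactly the flagged cell with the group-phase mean
  di <- build_design(co_miss, function(r) nrow(r$calls), "n_calls",
                     impute_missing = TRUE)
  miss_row <- which(d$missing)
  intact <- di$n_calls[!d$missing & di$group == di$group[miss_row] &
                         di$phase == di$phase[miss_row]]
  expect_equal(di$n_calls[miss_row], mean(intact))
  expect_equal(di$n_calls[-miss_row], d$n_calls[-miss_row])
})

test_that("metric failures name the subject and phase", {
  co <- small_cohort()
  expect_error(build_design(co, function(r) stop("boom")), "phase")
})

test_that("sign-flip enumeration has the right granularity and edge cases", {
  # all-zero deltas: p = 1, effect 0
  t0 <- signflip_test(c(0, 0, 0, 0))
  expect_equal(t0$p_value, 1)
  expect_equal(t0$estimate, 0)

  # n = 3: exact enumeration over 2^3 patterns, p a multiple of 1/8
  t3 <- signflip_test(c(1, 2, 3))
  expect_match(t3$method, "exact")
  expect_equal(t3$p_value * 8, round(t3$p_value * 8))

  # strong positive shift, n = 20 exact: p < 0.001 with positive direction
  withr::local_seed(41)
  d <- stats::rnorm(20, 30, 5)
  t20 <- signflip_test(d)
  expect_match(t20$method, "exact")
  expect_lt(t20$p_value, 0.001)
  expect_equal(t20$direction, 1)

  # exact enumeration agrees with brute force at small n
  dd <- c(1.3, -0.4, 2.1, 0.7)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  brute <- mean(abs(signs %*% dd) >= abs(sum(dd)) - 1e-12)
  expect_equal(signflip_test(dd)$p_value, brute)
})

test_that("potentiation contrasts pair phases and exclude incomplete subjects", {
  cfg <- default_cohort_config(n_per_cell = 3, litters_per_group = 2, seed = 5)
  co <- generate_cohort(cfg, phases = c("ISO1", "ISO2"))$cohort
  pot <- potentiation_test(co)
  expect_equal(pot$per_subject$delta,
               pot$per_subject$n_iso2 - pot$per_subject$n_iso1)
  expect_setequal(pot$per_group$group, c("VEH", "MAM"))
  # control group potentiated (multiplier 1.6): positive direction
  veh <- pot$per_group[pot$per_group$group == "VEH", ]
  expect_equal(veh$direction, 1)

  co_drop <- cohort(co$recordings[-1], label = "drop")
  expect_warning(pot2 <- potentiation_test(co_drop), "excluded")
  expect_equal(nrow(pot2$per_subject), nrow(pot$per_subject) - 1L)
})

make_design <- function(n_per_group = 16, litters = 4, shift = 0, seed = 1) {
  withr::with_seed(seed, {
    g <- rep(c("VEH", "MAM"), each = n_per_group)
    lit <- paste0(g, rep_len(seq_len(litters), n_per_group))
    tibble::tibble(subject = paste0("s", seq_along(g)), litter = lit,
                   group = g,
                   value = stats::rnorm(length(g)) + ifelse(g == "MAM", shift, 0))
  })
}

test_that("group contrasts are symmetric and respect litter blocks", {
  d <- make_design(shift = 1, seed = 2)
  a <- group_contrast(d, contrast = c("VEH", "MAM"))
  b <- group_contrast(d, contrast = c("MAM", "VEH"))
  expect_equal(a$estimate, -b$estimate)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$exchange_unit, "litter")

  # shuffling values within litters leaves the litter-exact p unchanged
  d2 <- d
  for (l in unique(d2$litter)) {
    ix <- which(d2$litter == l)
    d2$value[ix] <- d2$value[sample(ix)]
  }
  expect_equal(group_contrast(d2)$p_value, a$p_value)

  # single-litter group falls back to subject level with a warning
  d3 <- d
  d3$litter[d3$group == "MAM"] <- "M1"
  expect_warning(r3 <- group_contrast(d3, seed = 4), "fewer than 2 litters")
  expect_equal(r3$exchange_unit, "subject")
})

test_that("a 2-SD shift at 16 per group is detected in at least 80% of replicates", {
  hits <- vapply(1:200, function(i) {
    d <- make_design(shift = 2, seed = 1000 + i)
    group_contrast(d)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("the null rejection rate is calibrated", {
  p <- vapply(1:200, function(i) group_contrast(make_design(seed = 2000 + i))$p_value, 0)
  mc3 <- 3 * sqrt(0.05 * 0.95 / 200)
  expect_lte(mean(p < 0.05), 0.05 + mc3)
})

test_that("Monte Carlo p-values are seed-stable and order-invariant", {
  d <- make_design(n_per_group = 30, litters = 12, shift = 0.8, seed = 3)
  r1 <- group_contrast(d, n_perm = 999, seed = 7, exchange = "subject")
  r2 <- group_contrast(d, n_perm = 999, seed = 7, exchange = "subject")
  expect_identical(r1$p_value, r2$p_value)
  perm <- withr::with_seed(8, sample(nrow(d)))
  r3 <- group_contrast(d[perm, ], n_perm = 999, seed = 7, exchange = "subject")
  # two different orderings: p differs only by Monte-Carlo error
  expect_lt(abs(r3$p_value - r1$p_value), 3 / sqrt(999))
})

test_that("cluster proportion contrasts arcsine-transform and BH-adjust", {
  withr::local_seed(44)
  subj <- sprintf("s%02d", 1:16)
  d <- do.call(rbind, lapply(subj, function(s) {
    grp <- if (as.integer(substr(s, 2, 3)) <= 8) "VEH" else "MAM"
    p7 <- stats::runif(1, 0.4, 0.6) + if (grp == "MAM") 0.2 else 0
    tibble::tibble(subject = s, litter = paste0(grp, 1 + as.integer(substr(s, 2, 3)) %% 4),
                   group = grp, cluster = c(7L, 8L),
                   proportion = c(p7, 1 - p7))
  }))
  out <- cluster_proportion_contrast(d, n_perm = 99, seed = 1)
  expect_equal(nrow(out), 2L)
  expect_gt(out$effect_raw[out$cluster == 7], 0)
  expect_true(all(out$p_adj >= out$p_value))

  # closed-form identities of the transform
  expect_equal(asin(sqrt(0)), 0)
  expect_equal(asin(sqrt(1)), pi / 2)
  expect_equal(asin(sqrt(0.5)), pi / 4)

  d_bad <- d; d_bad$proportion[1] <- 1.2
  expect_error(cluster_proportion_contrast(d_bad),
               class = "pupsyntax_validation_error")

  # constant proportions across groups: zero effect
  d_const <- d; d_const$proportion <- rep(c(0.5, 0.5), 16)
  out0 <- cluster_proportion_contrast(d_const, n_perm = 99, seed = 1)
  expect_true(all(abs(out0$effect_raw) < 1e-12))
})
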