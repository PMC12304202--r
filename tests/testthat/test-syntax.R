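# Within-bout transition models and group comparison.

test_that("the worked four-call bout yields the textbook model", {
  rec <- labeled_recording(c(7L, 7L, 1L, 7L), c(50, 50, 50))
  pairs <- collect_transitions(rec)
  expect_equal(nrow(pairs), 3L)
  expect_equal(paste(pairs$source, pairs$target),
               c("7 7", "7 1", "1 7"))

  m <- build_transition_model(pairs)
  expect_equal(m$cond_prob["7", c("7", "1")], c(`7` = 0.5, `1` = 0.5))
  expect_equal(unname(m$cond_prob["1", "7"]), 1)
  expect_equal(unname(m$joint_freq["7", "7"]), 1 / 3)
  expect_equal(unname(m$column_sums["7"]), 1.5)
  expect_equal(unname(m$column_sums["1"]), 0.5)

  prof <- column_sum_profile(m)
  expect_equal(prof$cluster, c(1L, 7L))   # ascending scores
  expect_equal(prof$score, c(0.5, 1.5))
})

test_that("pairs never cross bout boundaries and singleton bouts contribute none", {
  rec <- labeled_recording(c(7L, 1L, 8L), c(50, 2500))
  pairs <- collect_transitions(rec)
  expect_equal(nrow(pairs), 1L)
  expect_equal(c(pairs$source, pairs$target), c(7L, 1L))

  empty <- recording(call_table(), subject_id = "e")
  expect_equal(nrow(collect_transitions(empty)), 0L)

  # inserting a >= 2000 ms gap removes exactly one pair
  before <- collect_transitions(labeled_recording(c(7L, 7L, 1L, 7L), c(50, 50, 50)))
  after <- collect_transitions(labeled_recording(c(7L, 7L, 1L, 7L), c(50, 2000, 50)))
  expect_equal(nrow(before) - nrow(after), 1L)
})

test_that("unclassified calls are reported by row", {
  rec <- labeled_recording(c(7L, NA, 1L), c(50, 50))
  expect_error(collect_transitions(rec), "unclassified")
})

test_that("the 0.01 exclusion is strictly below, retention at exactly 0.01", {
  mk_pairs <- function(n77, n71) {
    tibble::tibble(source = rep(7L, n77 + n71),
                   target = c(rep(7L, n77), rep(1L, n71)),
                   recording = "r", group = "VEH")
  }
  m1 <- build_transition_model(mk_pairs(199, 1))   # freq 0.005 -> excluded
  expect_false(m1$retained["7", "1"])
  m2 <- build_transition_model(mk_pairs(198, 2))   # freq exactly 0.01 -> retained
  expect_true(m2$retained["7", "1"])

  # a single dominant pair type keeps everything else excluded
  m3 <- build_transition_model(mk_pairs(100, 0))
  expect_equal(unname(m3$joint_freq["7", "7"]), 1)
  expect_equal(sum(m3$retained), 1L)
})

test_that("transition algebra holds under fuzzing, with brute-force column sums", {
  withr::local_seed(31)
  for (i in 1:200) {
    n <- sample(1:500, 1)
    pairs <- tibble::tibble(source = sample(1:8, n, replace = TRUE),
                            target = sample(1:8, n, replace = TRUE),
                            recording = "r", group = "VEH")
    m <- build_transition_model(pairs)
    expect_equal(sum(m$joint_freq), 1, tolerance = 1e-12)
    rs <- rowSums(m$counts)
    nonzero <- rs > 0
    expect_true(all(abs(rowSums(m$cond_prob)[nonzero] - 1) < 1e-12))
    expect_identical(m$retained, m$joint_freq >= 0.01)
    expect_equal(unname(m$column_sums), brute_column_sums(m), tolerance = 1e-12)
  }
})

test_that("renormalisation restores row-stochasticity after exclusion", {
  withr::local_seed(32)
  pairs <- tibble::tibble(source = sample(1:4, 400, replace = TRUE),
                          target = sample(1:4, 400, replace = TRUE),
                          recording = "r", group = "VEH")
  m <- build_transition_model(pairs, renormalize = TRUE)
  kept_rows <- rowSums(m$counts * m$retained) > 0
  sums <- rowSums(m$cond_prob * m$retained /
                    ifelse(rowSums(m$cond_prob * m$retained) > 0,
                           rowSums(m$cond_prob * m$retained), 1))
  expect_equal(unname(m$column_sums), unname(colSums(
    (m$cond_prob * m$retained) / ifelse(rowSums(m$cond_prob * m$retained) > 0,
                                        rowSums(m$cond_prob * m$retained), 1))),
    tolerance = 1e-12)
})

test_that("a simulated Markov chain is recovered within 0.03 per entry", {
  withr::local_seed(33)
  tm <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3), c(0.1, 0.1, 0.8))
  n <- 10001
  states <- integer(n)
  states[1] <- 1L
  for (i in 2:n) states[i] <- sample.int(3, 1, prob = tm[states[i - 1], ])
  pairs <- tibble::tibble(source = states[-n], target = states[-1],
                          recording = "r", group = "VEH")
  m <- build_transition_model(pairs, min_joint_freq = 0)
  expect_lt(max(abs(m$cond_prob - tm)), 0.03)
})

test_that("group comparison is null for identical groups and localises a contrast", {
  withr::local_seed(34)
  mk_rec <- function(id, labels, group) {
    labeled_recording(labels, rep(50, length(labels) - 1), subject = id,
                      group = group, litter = substr(id, 1, 2))
  }
  labs <- replicate(4, sample(c(7L, 7L, 7L, 1L, 8L), 12, replace = TRUE),
                    simplify = FALSE)
  recs_a <- lapply(1:4, function(i) mk_rec(paste0("A", i), labs[[i]], "VEH"))
  recs_b <- lapply(1:4, function(i) mk_rec(paste0("B", i), labs[[i]], "MAM"))
  pairs <- collect_transitions(c(recs_a, recs_b))
  cmp <- compare_transition_profiles(pairs, n_perm = 99, seed = 9)
  expect_true(all(abs(cmp$edge_diff) < 1e-12))
  expect_true(all(abs(cmp$column_diff) < 1e-12))

  # determinism: identical seeds give identical p-values
  cmp2 <- compare_transition_profiles(pairs, n_perm = 99, seed = 9)
  expect_identical(cmp$edge_p, cmp2$edge_p)
  expect_identical(cmp$column_p, cmp2$column_p)

  # rewriting all 1-labels to 7 in group B concentrates differences on 1/7
  labs_b <- lapply(labs, function(l) replace(l, l == 1L, 7L))
  recs_b2 <- lapply(1:4, function(i) mk_rec(paste0("B", i), labs_b[[i]], "MAM"))
  pairs2 <- collect_transitions(c(recs_a, recs_b2))
  cmp3 <- compare_transition_profiles(pairs2, n_perm = 99, seed = 9)
  touched <- unique(c(which(abs(cmp3$edge_diff) > 1e-12, arr.ind = TRUE)))
  lbl <- cmp3$labels
  involved <- apply(which(abs(cmp3$edge_diff) > 1e-12, arr.ind = TRUE), 1,
                    function(ij) any(lbl[ij] %in% c(1, 7)))
  expect_true(all(involved))
  expect_gt(cmp3$column_diff[as.character(7)], 0)

  expect_error(compare_transition_profiles(pairs[pairs$recording == "A1", ]),
               "at least 2")
})

test_that("transition tables and DOT graphs export", {
  rec <- labeled_recording(rep(c(7L, 1L), 10), rep(50, 19))
  m <- build_transition_model(collect_transitions(rec))
  f <- withr::local_tempfile(fileext = ".csv")
  write_transition_table(m, f)
  back <- utils::read.csv(f, row.names = 1)
  expect_equal(as.matrix(back), m$cond_prob, ignore_attr = TRUE)
  dot <- transition_dot(m)
  expect_match(dot, "digraph")
  expect_match(dot, "c7 -> c1")
})
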