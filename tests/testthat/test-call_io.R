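# Readers, writers, merge rule, cohort manifests.

write_raven_fixture <- function(path, rows) {
  header <- paste(c("Selection", "View", "Channel", "Begin Time (s)",
                    "End Time (s)", "Low Freq (Hz)", "High Freq (Hz)"),
                  collapse = "\t")
  writeLines(c(header, rows), path)
}

test_that("Raven selection tables convert Hz to kHz and derive durations", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_raven_fixture(f, c(
    "1\tSpectrogram 1\t1\t1.000\t1.050\t38000\t43000",
    "2\tSpectrogram 1\t1\t2.000\t2.020\t55000\t60000"))
  rec <- read_raven_selection_table(f, list(subject_id = "p1"))
  expect_equal(nrow(rec$calls), 2L)
  expect_equal(rec$calls$duration, c(50, 20))
  expect_equal(rec$calls$bandwidth, c(5, 5))
  # no Peak Freq column: midpoint fallback, flagged approximate
  expect_equal(rec$calls$peak_frequency, c(40.5, 57.5))
  expect_true(all(rec$calls$peak_approximate))
})

test_that("Raven reader handles empty tables and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_raven_fixture(f, character())
  expect_equal(nrow(read_raven_selection_table(f)$calls), 0L)

  write_raven_fixture(f, "1\tSpectrogram 1\t1\t2.000\t1.500\t38000\t43000")
  expect_error(read_raven_selection_table(f), class = "pupsyntax_validation_error")

  writeLines(c("Begin Time (s)\tEnd Time (s)\tLow Freq (Hz)",
               "1.0\t1.1\t38000"), f)
  expect_error(read_raven_selection_table(f), "High Freq",
               class = "pupsyntax_format_error")
})

test_that("DeepSqueak CSVs parse with synonym columns and duration arithmetic", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Begin Time (s),Call Length (s),Principal Frequency (kHz),Delta Freq (kHz)",
               "0.5,0.1,40,6"), f)
  rec <- read_deepsqueak_csv(f, list(subject_id = "p1"))
  expect_equal(rec$calls$offset, 0.6)
  expect_equal(rec$calls$duration, 100)
  expect_equal(rec$calls$peak_frequency, 40)
  expect_false(rec$calls$peak_approximate)

  # header only -> zero calls
  writeLines("BeginTime,CallLength,PeakFreq,DeltaFreq", f)
  expect_equal(nrow(read_deepsqueak_csv(f)$calls), 0L)
})

test_that("duplicated detections are kept with an overlap warning", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Begin Time (s),Call Length (s),Principal Frequency (kHz),Delta Freq (kHz)",
               "0.5,0.1,40,6", "0.5,0.1,40,6"), f)
  expect_warning(rec <- read_deepsqueak_csv(f), "overlap")
  expect_equal(nrow(rec$calls), 2L)
})

test_that("end-time column wins over an inconsistent duration column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste("Begin Time (s),End Time (s),Call Length (s),",
                     "Principal Frequency (kHz),Delta Freq (kHz)", sep = ""),
               "0.5,0.65,0.1,40,6"), f)
  expect_warning(rec <- read_deepsqueak_csv(f), "times win")
  expect_equal(rec$calls$duration, 150)
})

test_that("both dialects round-trip randomized call tables", {
  withr::local_seed(42)
  n <- 1000
  onset <- cumsum(stats::runif(n, 0.06, 0.5))
  dur <- stats::runif(n, 0.005, 0.045)
  calls <- call_table(onset = onset, offset = onset + dur,
                      peak_frequency = stats::runif(n, 20, 120),
                      bandwidth = stats::runif(n, 0, 40),
                      slope = stats::runif(n, -800, 800),
                      cluster = sample(1:8, n, replace = TRUE),
                      source_id = as.character(seq_len(n)))
  rec <- recording(calls, subject_id = "rt", sex = "F", group = "VEH",
                   phase = "DEV9", duration = max(onset + dur) + 5)
  for (dialect in c("raven", "csv")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_call_table(rec, f, dialect)
    back <- if (dialect == "raven") {
      read_raven_selection_table(f, list(subject_id = "rt", duration = rec$duration))
    } else {
      read_deepsqueak_csv(f, list(subject_id = "rt", duration = rec$duration))
    }
    for (col in c("onset", "offset", "duration", "peak_frequency", "bandwidth", "slope")) {
      expect_equal(back$calls[[col]], calls[[col]], tolerance = 1e-6,
                   label = paste(dialect, col))
    }
    expect_equal(back$calls$cluster, calls$cluster)
  }
})

test_that("the raven dialect writes the standard column header", {
  calls <- call_table(onset = 1, offset = 1.05, peak_frequency = 40,
                      bandwidth = 5, slope = 10, cluster = 7L, source_id = "1")
  rec <- recording(calls, subject_id = "h")
  f <- withr::local_tempfile(fileext = ".txt")
  write_call_table(rec, f, "raven")
  header <- strsplit(readLines(f, n = 1L), "\t")[[1]]
  expect_identical(header[1:8],
                   c("Selection", "View", "Channel", "Begin Time (s)",
                     "End Time (s)", "Low Freq (Hz)", "High Freq (Hz)",
                     "Peak Freq (Hz)"))
})

test_that("unknown dialect is an argument error", {
  rec <- recording(call_table(), subject_id = "x")
  expect_error(write_call_table(rec, tempfile(), "parquet"))
})

test_that("detections separated by less than 10 ms are merged at load", {
  calls <- call_table(onset = c(1.000, 1.055, 1.200),
                      offset = c(1.050, 1.100, 1.250),
                      peak_frequency = c(40, 50, 60),
                      bandwidth = c(4, 10, 5),
                      source_id = c("a", "b", "c"))
  merged <- merge_close_calls(calls, 10)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$onset[1], 1.000)
  expect_equal(merged$offset[1], 1.100)
  # union band: low = min(40-2, 50-5) = 38, high = max(40+2, 50+5) = 55
  expect_equal(merged$bandwidth[1], 55 - 38)
  expect_equal(merged$peak_frequency[1], 50)  # widest-band fragment
  expect_identical(merge_close_calls(calls, NULL), calls)
})

test_that("merging is idempotent and sorting is stable", {
  withr::local_seed(7)
  n <- 50
  onset <- cumsum(stats::runif(n, 0.001, 0.2))
  calls <- call_table(onset = onset, offset = onset + 0.005,
                      peak_frequency = 50, bandwidth = 5,
                      source_id = as.character(1:n))
  m1 <- merge_close_calls(calls, 10)
  m2 <- merge_close_calls(m1, 10)
  expect_equal(m1$onset, m2$onset)
  expect_equal(m1$offset, m2$offset)
  expect_false(is.unsorted(m1$onset))
})

make_manifest <- function(dir, groups, litters) {
  paths <- character(length(groups))
  for (i in seq_along(groups)) {
    p <- file.path(dir, sprintf("rec%d.txt", i))
    write_raven_fixture(p, sprintf(
      "1\tSpectrogram 1\t1\t%.3f\t%.3f\t38000\t43000", 1 + i / 10, 1.05 + i / 10))
    paths[i] <- basename(p)
  }
  man <- data.frame(subject_id = paste0("s", seq_along(groups)),
                    litter_id = litters, sex = "F", group = groups,
                    pnd = 6, phase = "DEV6", duration_s = 300,
                    calltable_path = paths)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mf, row.names = FALSE)
  mf
}

test_that("cohort manifests load with group counts and validation", {
  dir <- withr::local_tempdir()
  mf <- make_manifest(dir, c("VEH", "VEH", "MAM", "MAM"), c("A", "A", "B", "B"))
  expect_message(co <- load_cohort(mf), "VEH")
  s <- summarize_cohort(co)
  expect_equal(sort(s$by_group_sex$n_recordings), c(2L, 2L))

  # litter in two groups is a consistency error
  dir2 <- withr::local_tempdir()
  mf2 <- make_manifest(dir2, c("VEH", "MAM"), c("A", "A"))
  expect_error(suppressMessages(load_cohort(mf2)), "litter",
               class = "pupsyntax_consistency_error")

  # missing call table is an I/O error naming the path
  dir3 <- withr::local_tempdir()
  mf3 <- make_manifest(dir3, "VEH", "A")
  file.remove(file.path(dir3, "rec1.txt"))
  expect_error(load_cohort(mf3), "rec1.txt", class = "pupsyntax_io_error")
})

test_that("call-table invariants are enforced", {
  expect_error(call_table(onset = 1, offset = 0.5, peak_frequency = 40,
                          bandwidth = 2),
               class = "pupsyntax_validation_error")
  expect_error(
    recording(call_table(onset = 1, offset = 400, peak_frequency = 40,
                         bandwidth = 2),
              subject_id = "x", duration = 300),
    class = "pupsyntax_validation_error")
  expect_error(recording(call_table(), subject_id = "x", phase = "ISO1",
                         pnd = 9),
               "postnatal day 10")
})
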