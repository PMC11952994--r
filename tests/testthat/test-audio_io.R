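test_that("WAV round-trip is identity within 16-bit quantization", {
  path <- withr::local_tempfile(fileext = ".wav")

  write_wav(recording(numeric(44100), 44100), path)
  rec <- read_wav(path)
  expect_length(rec$samples, 44100)
  expect_true(all(rec$samples == 0))
  expect_identical(rec$sample_rate_hz, 44100L)

  x <- sine_wave(440, 0.25, rate = 44100, amp = 0.8)
  write_wav(recording(x, 44100), path)
  back <- read_wav(path)
  expect_lt(max(abs(back$samples - x)), 1 / 32767)

  write_wav(recording(x, 44100), path, bit_depth = 32L)
  back32 <- read_wav(path)
  expect_lt(max(abs(back32$samples - x)), 1e-7)
})

test_that("multi-channel WAV is averaged to mono with a notice", {
  path <- withr::local_tempfile(fileext = ".wav")
  # hand-built stereo PCM16 file: L = 0.5, R = -0.5 throughout
  n <- 1000L
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n * 4L), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(c(8000L, 32000L), con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * 4L), con, size = 4, endian = "little")
  writeBin(rep(c(16384L, -16384L), n), con, size = 2, endian = "little")
  close(con)
  expect_message(rec <- read_wav(path), "averaged 2 channels")
  expect_length(rec$samples, n)
  expect_true(all(abs(rec$samples) < 1e-9))
})

test_that("recording constructor enforces its invariants", {
  expect_error(recording(numeric(0), 44100), "at least one sample")
  expect_error(recording(c(0, NA), 44100), "finite")
  expect_error(recording(0.5, 4000), ">= 8000")
  expect_error(recording(1.5, 44100), "\\[-1, 1\\]")
})

test_that("label validation accepts half-open adjacency and rejects overlap", {
  ok <- data.frame(event_type = c("exhalation", "inhalation"),
                   start_s = c(0, 2), end_s = c(2, 4))
  expect_silent(out <- validate_labels(ok))
  expect_equal(nrow(out), 2L)

  bad <- data.frame(event_type = c("exhalation", "exhalation"),
                    start_s = c(0, 1.5), end_s = c(2, 3))
  expect_error(validate_labels(bad), "overlap")
  expect_error(validate_labels(data.frame(event_type = "exhalation",
                                          start_s = 2, end_s = 2)),
               "start_s < end_s")
  expect_error(validate_labels(data.frame(event_type = "cough",
                                          start_s = 0, end_s = 1)),
               "unknown event_type")
  expect_error(validate_labels(ok, duration_s = 3), "past recording end")
})

test_that("labels TSV reads the full task and rejects malformed rows", {
  fx <- burst_recording()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labels(cbind(recording_id = "T01_step00", fx$labels), path)
  labs <- read_labels(path)
  expect_named(labs, "T01_step00")
  tab <- table(labs[["T01_step00"]]$event_type)
  expect_equal(as.integer(tab[c("inhalation", "exhalation", "vowel")]),
               c(3L, 3L, 1L))

  bad <- data.frame(recording_id = "r", event_type = "exhalation",
                    start_s = c(0, 1), end_s = c(2, 3))
  write_labels(bad, path)
  expect_error(read_labels(path), "overlap")
})

test_that("biomarker table has the 84-column schema and round-trips", {
  rows <- data.frame(subject_id = "S01", step_index = 0:4,
                     cumulative_dose_mcg = c(0, 100, 200, 400, 800),
                     fev1_l = seq(3.4, 3.0, length.out = 5))
  for (b in c(paste0("mu_", 1:40), paste0("sigma_", 1:40)))
    rows[[b]] <- round(stats::rnorm(5), 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_biomarker_table(rows, path)
  back <- read_biomarker_table(path)
  expect_equal(ncol(back), 84L)
  expect_equal(nrow(back), 5L)
  expect_equal(back$mu_17, rows$mu_17, tolerance = 1e-12)

  expect_error(write_biomarker_table(rows[, -4], path), "fev1_l")
  dup <- rbind(rows, rows[1, ])
  expect_error(write_biomarker_table(dup, path), "duplicate")
})

test_that("session table round-trips and validates", {
  df <- data.frame(subject_id = c("A", "A", "B"), step_index = c(0L, 1L, 0L),
                   cumulative_dose_mcg = c(0, 100, 0), fev1_l = c(3.2, 3.0, 4.1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_table(df, path)
  expect_equal(read_session_table(path), df, ignore_attr = TRUE)
  df$fev1_l[2] <- -1
  write.csv(df, path, row.names = FALSE)
  expect_error(read_session_table(path), "positive")
})
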