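#' Construct a recording object
#'
#' A recording is a mono waveform with its sampling rate and the session
#' coordinates (subject, challenge step, task) it belongs to. Amplitudes are
#' dimensionless in \[-1, 1\].
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\].
#' @param sample_rate_hz positive integer sampling rate (nominally 44100);
#'   must be at least 8000.
#' @param subject_id,task_id opaque identifier strings.
#' @param step_index non-negative integer challenge step (0 = saline).
#' @return An object of class `vb_recording`.
#' @export
recording <- function(samples, sample_rate_hz, subject_id = "unknown",
                      step_index = 0L, task_id = "task") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop_validation("recording must hold at least one sample")
  if (!all(is.finite(samples))) stop_validation("recording samples must be finite")
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (is.na(sample_rate_hz) || sample_rate_hz < 8000L)
    stop_validation("sample_rate_hz must be an integer >= 8000")
  if (min(samples) < -1 || max(samples) > 1)
    stop_validation("recording amplitudes must lie in [-1, 1]")
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         subject_id = as.character(subject_id),
         step_index = as.integer(step_index),
         task_id = as.character(task_id)),
    class = "vb_recording")
}

#' @export
print.vb_recording <- function(x, ...) {
  cat(sprintf("<vb_recording> subject %s step %d: %.3f s @ %d Hz\n",
              x$subject_id, x$step_index, duration_s(x), x$sample_rate_hz))
  invisible(x)
}

#' Duration of a recording or segment in seconds
#' @param x a `vb_recording` or `vb_segment`.
#' @return Duration in seconds.
#' @export
duration_s <- function(x) length(x$samples) / x$sample_rate_hz

## ---- WAV ------------------------------------------------------------------
# Minimal RIFF/WAVE reader and writer (mono or interleaved multi-channel,
# PCM16 or IEEE float32). Only the fmt and data chunks are interpreted;
# other chunks are skipped.

#' Read a WAV file as a recording
#'
#' Supports PCM 16-bit and IEEE float 32-bit WAV. Multi-channel audio is
#' reduced to mono by averaging the channels (with a notice), since phone
#' recordings vary in channel layout. PCM amplitudes are normalised by 32768
#' so output lies in \[-1, 1\].
#'
#' @param path path to an existing WAV file.
#' @param subject_id,step_index,task_id session coordinates to attach.
#' @return A [recording()].
#' @export
read_wav <- function(path, subject_id = "unknown", step_index = 0L,
                     task_id = "task") {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("corrupt WAV (no RIFF header): ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("corrupt WAV (no WAVE id): ", path)

  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels   = readBin(raw_fmt[3:4], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        sample_rate  = readBin(raw_fmt[5:8], "integer", 1, size = 4,
                               endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1, size = 2,
                               endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("corrupt WAV (data before fmt): ", path)
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", size / 2, size = 2,
                           endian = "little") / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", size / 4, size = 4,
                           endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d bit): %s",
                     fmt$audio_format, fmt$bits, path))
      }
      if (size %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip, chunks are word-aligned
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples) || length(samples) == 0L)
    stop("corrupt WAV (no data chunk): ", path)
  if (fmt$n_channels > 1L) {
    usable <- length(samples) - length(samples) %% fmt$n_channels
    samples <- rowMeans(matrix(samples[seq_len(usable)],
                               ncol = fmt$n_channels, byrow = TRUE))
    message("read_wav: averaged ", fmt$n_channels, " channels to mono")
  }
  samples <- pmin(1, pmax(-1, samples))
  recording(samples, fmt$sample_rate, subject_id = subject_id,
            step_index = step_index, task_id = task_id)
}

#' Write a recording to a WAV file
#'
#' @param rec a [recording()] (or bare numeric vector with `sample_rate_hz`).
#' @param path output path.
#' @param bit_depth 16 (PCM) or 32 (IEEE float).
#' @param sample_rate_hz used only when `rec` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bit_depth = 16L, sample_rate_hz = NULL) {
  if (!inherits(rec, "vb_recording")) {
    if (is.null(sample_rate_hz))
      stop("sample_rate_hz is required when writing a bare vector")
    rec <- recording(rec, sample_rate_hz)
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(16L, 32L)) stop("bit_depth must be 16 or 32")
  x <- rec$samples
  n <- length(x)
  bytes_per <- bit_depth %/% 8L
  data_size <- n * bytes_per
  fmt_code <- if (bit_depth == 16L) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(rec$sample_rate_hz, con, size = 4, endian = "little")
  writeBin(rec$sample_rate_hz * bytes_per, con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(bit_depth, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16L) {
    writeBin(as.integer(pmin(32767, pmax(-32768, round(x * 32768)))),
             con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

## ---- Event labels ---------------------------------------------------------

EVENT_TYPES <- c("inhalation", "exhalation", "vowel")

#' Validate event labels for one recording
#'
#' Labels are half-open time intervals `[start_s, end_s)` in seconds from the
#' start of the recording. Labels of the same recording must not overlap
#' (shared boundaries are allowed), must have `end_s > start_s >= 0`, and must
#' use a known event type.
#'
#' @param labels data frame with columns `event_type`, `start_s`, `end_s`
#'   (extra columns such as `recording_id` or `quality_note` are kept).
#' @param duration_s optional recording duration; when given, labels must not
#'   extend past it.
#' @return The labels, sorted by `start_s`.
#' @export
validate_labels <- function(labels, duration_s = NULL) {
  need <- c("event_type", "start_s", "end_s")
  miss <- setdiff(need, names(labels))
  if (length(miss))
    stop_validation(paste("labels missing column(s):", paste(miss, collapse = ", ")))
  labels$event_type <- as.character(labels$event_type)
  bad_type <- which(!labels$event_type %in% EVENT_TYPES)
  if (length(bad_type))
    stop_validation(sprintf("row %d: unknown event_type '%s'",
                            bad_type[1], labels$event_type[bad_type[1]]))
  bad_span <- which(!(labels$start_s >= 0 & labels$end_s > labels$start_s))
  if (length(bad_span))
    stop_validation(sprintf("row %d: need 0 <= start_s < end_s", bad_span[1]))
  if (!is.null(duration_s)) {
    past <- which(labels$end_s > duration_s + 1e-9)
    if (length(past))
      stop_validation(sprintf("row %d: label ends at %.3f s, past recording end (%.3f s)",
                              past[1], labels$end_s[past[1]], duration_s))
  }
  labels <- labels[order(labels$start_s), , drop = FALSE]
  if (nrow(labels) > 1L) {
    ov <- which(labels$start_s[-1] < labels$end_s[-nrow(labels)] - 1e-12)
    if (length(ov))
      stop_validation(sprintf("rows %d and %d: overlapping labels", ov[1], ov[1] + 1L))
  }
  rownames(labels) <- NULL
  labels
}

#' Read event labels from a TSV file
#'
#' Expects a UTF-8, tab-separated file with header columns `recording_id`,
#' `event_type`, `start_s`, `end_s` (optional `quality_note`). Labels are
#' validated per recording and returned sorted by start time.
#'
#' @param path TSV path.
#' @return A named list of label data frames, one per `recording_id`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("recording_id", "event_type", "start_s", "end_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation(paste("label TSV missing column(s):", paste(miss, collapse = ", ")))
  lapply(split(df, df$recording_id), validate_labels)
}

#' Write event labels to a TSV file
#' @param labels data frame with columns `recording_id`, `event_type`,
#'   `start_s`, `end_s`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

## ---- Session and biomarker tables -----------------------------------------

biomarker_ids <- function() c(paste0("mu_", 1:40), paste0("sigma_", 1:40))

check_unique_keys <- function(df, what) {
  key <- paste(df$subject_id, df$step_index)
  if (anyDuplicated(key))
    stop_validation(paste0("duplicate (subject_id, step_index) key in ", what,
                           ": ", key[duplicated(key)][1]))
}

#' Read a per-subject session table
#'
#' A session table has one row per challenge step:
#' `subject_id, step_index, cumulative_dose_mcg, fev1_l`.
#'
#' @param path CSV path.
#' @return A data frame sorted by subject then step.
#' @export
read_session_table <- function(path) {
  if (!file.exists(path)) stop("session table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "step_index", "cumulative_dose_mcg", "fev1_l")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation(paste("session table missing column(s):",
                          paste(miss, collapse = ", ")))
  check_unique_keys(df, "session table")
  if (any(df$fev1_l <= 0)) stop_validation("fev1_l must be positive")
  df[order(df$subject_id, df$step_index), , drop = FALSE]
}

#' Write a session table
#' @param df session data frame (see [read_session_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_table <- function(df, path) {
  check_unique_keys(df, "session table")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read biomarker tables
#'
#' A biomarker table holds, per (subject, step), the session covariates and
#' the 80 aggregated biomarkers of one sound type: columns `subject_id`,
#' `step_index`, `cumulative_dose_mcg`, `fev1_l`, `mu_1..mu_40`,
#' `sigma_1..sigma_40` (84 columns).
#'
#' @param rows biomarker data frame.
#' @param path CSV path.
#' @return `write_biomarker_table()` returns `path` invisibly;
#'   `read_biomarker_table()` returns the validated data frame.
#' @export
write_biomarker_table <- function(rows, path) {
  cols <- c("subject_id", "step_index", "cumulative_dose_mcg", "fev1_l",
            biomarker_ids())
  miss <- setdiff(cols, names(rows))
  if (length(miss))
    stop_validation(paste("biomarker table missing column(s):",
                          paste(miss[seq_len(min(4, length(miss)))], collapse = ", ")))
  check_unique_keys(rows, "biomarker table")
  write.csv(rows[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_biomarker_table
#' @export
read_biomarker_table <- function(path) {
  if (!file.exists(path)) stop("biomarker table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("subject_id", "step_index", "cumulative_dose_mcg", "fev1_l",
            biomarker_ids())
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_validation(paste("biomarker table missing column(s):",
                          paste(miss[seq_len(min(4, length(miss)))], collapse = ", ")))
  check_unique_keys(df, "biomarker table")
  df
}
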