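#' Quality-gate thresholds
#'
#' Thresholds for the recording quality evaluator. The defaults are
#' conventional field-recording heuristics: a clipped-sample fraction above
#' 1\% fails ("clipped"), an event-vs-gap signal-to-noise ratio below 5 dB
#' fails ("noisy"), and any labeled event shorter than 0.2 s fails
#' ("interrupted").
#'
#' @param max_clipping_fraction maximum tolerated fraction of samples at the
#'   amplitude rail.
#' @param min_snr_db minimum labeled-event vs unlabeled-gap SNR in decibels.
#' @param min_event_s minimum labeled event duration in seconds.
#' @return A list of class `vb_quality_thresholds`.
#' @export
quality_thresholds <- function(max_clipping_fraction = 0.01,
                               min_snr_db = 5,
                               min_event_s = 0.2) {
  structure(list(max_clipping_fraction = max_clipping_fraction,
                 min_snr_db = min_snr_db,
                 min_event_s = min_event_s),
            class = "vb_quality_thresholds")
}

# Half-open [start_s, end_s) -> 1-based sample index range; sample index of
# time t is floor(t * rate), so boundary samples are never double counted.
# A sub-sample epsilon absorbs float rounding in times that are exact sample
# multiples.
label_sample_range <- function(start_s, end_s, rate, n) {
  from <- floor(start_s * rate + 1e-6) + 1L
  to <- floor(end_s * rate + 1e-6)
  if (from < 1L || to > n)
    stop_validation(sprintf("label [%.3f, %.3f) lies outside the recording span",
                            start_s, end_s))
  c(from, to)
}

#' Evaluate recording quality
#'
#' Computes a deterministic quality report for a recording and its labels:
#' the fraction of clipped samples (|x| at or above 0.999 of full scale), the
#' event-vs-gap SNR `10 log10(mean event power / mean gap power)` where gaps
#' are the unlabeled portions of the recording, and the total labeled event
#' duration. A recording passes if and only if no failure reason is recorded;
#' failed recordings are excluded from feature extraction downstream.
#'
#' @param rec a [recording()].
#' @param labels validated label data frame for this recording.
#' @param thresholds a [quality_thresholds()] object.
#' @return A list of class `vb_quality_report` with fields
#'   `clipping_fraction`, `snr_db`, `total_event_duration_s`, `passed`,
#'   `reasons`.
#' @export
evaluate_quality <- function(rec, labels, thresholds = quality_thresholds()) {
  stopifnot(inherits(rec, "vb_recording"))
  labels <- validate_labels(labels, duration_s(rec))
  x <- rec$samples
  n <- length(x)
  reasons <- character()

  clipping <- mean(abs(x) >= 0.999)
  if (clipping > thresholds$max_clipping_fraction) reasons <- c(reasons, "clipped")

  if (max(abs(x)) < 1e-6) reasons <- c(reasons, "silent")

  total_event <- if (nrow(labels)) sum(labels$end_s - labels$start_s) else 0
  if (nrow(labels) == 0L) reasons <- c(reasons, "no_events")
  if (nrow(labels) && any(labels$end_s - labels$start_s < thresholds$min_event_s))
    reasons <- c(reasons, "interrupted")

  snr_db <- NA_real_
  if (nrow(labels)) {
    in_event <- logical(n)
    for (i in seq_len(nrow(labels))) {
      rng <- label_sample_range(labels$start_s[i], labels$end_s[i],
                                rec$sample_rate_hz, n)
      in_event[rng[1]:rng[2]] <- TRUE
    }
    if (any(!in_event)) {
      ev_pow <- mean(x[in_event]^2)
      gap_pow <- mean(x[!in_event]^2)
      snr_db <- if (gap_pow == 0) {
        if (ev_pow == 0) -Inf else Inf
      } else 10 * log10(ev_pow / gap_pow)
      if (ev_pow == 0) snr_db <- -Inf
      if (snr_db < thresholds$min_snr_db) reasons <- c(reasons, "noisy")
    } else {
      message("evaluate_quality: no unlabeled gaps; SNR check skipped")
    }
  }

  structure(list(clipping_fraction = clipping,
                 snr_db = snr_db,
                 total_event_duration_s = total_event,
                 passed = length(reasons) == 0L,
                 reasons = reasons),
            class = "vb_quality_report")
}

#' @export
print.vb_quality_report <- function(x, ...) {
  cat(sprintf("<vb_quality_report> %s  clipping %.4f  SNR %.1f dB  events %.2f s%s\n",
              if (x$passed) "PASS" else "FAIL", x$clipping_fraction, x$snr_db,
              x$total_event_duration_s,
              if (length(x$reasons)) paste0("  [", paste(x$reasons, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Cut a recording into labeled event segments
#'
#' Produces one segment per label, samples taken on the half-open interval
#' `[start_s, end_s)` (sample index `floor(t * rate)`), label order preserved
#' by start time.
#'
#' @param rec a [recording()].
#' @param labels validated label data frame.
#' @return A list of `vb_segment` objects with fields `samples`,
#'   `sample_rate_hz`, `event_type`, `duration_s`, `start_s`.
#' @export
segment_events <- function(rec, labels) {
  stopifnot(inherits(rec, "vb_recording"))
  labels <- validate_labels(labels, duration_s(rec))
  n <- length(rec$samples)
  lapply(seq_len(nrow(labels)), function(i) {
    rng <- label_sample_range(labels$start_s[i], labels$end_s[i],
                              rec$sample_rate_hz, n)
    samples <- rec$samples[rng[1]:rng[2]]
    structure(list(samples = samples,
                   sample_rate_hz = rec$sample_rate_hz,
                   event_type = labels$event_type[i],
                   duration_s = length(samples) / rec$sample_rate_hz,
                   start_s = labels$start_s[i]),
              class = "vb_segment")
  })
}

#' Group event segments by sound type
#'
#' @param segments list of `vb_segment` from [segment_events()].
#' @return A named list mapping event type to its ordered segments; types with
#'   no segments are absent.
#' @export
group_events <- function(segments) {
  if (!length(segments)) return(setNames(list(), character()))
  types <- vapply(segments, function(s) s$event_type, character(1))
  out <- lapply(intersect(EVENT_TYPES, unique(types)),
                function(tp) segments[types == tp])
  setNames(out, intersect(EVENT_TYPES, unique(types)))
}
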