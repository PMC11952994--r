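# Assembly of the 40-parameter vectors and their mu/sigma aggregation.
#
# Feature routing: shape features (centroid, spread, flatness, roll-off) are
# measured on the resonance-enhanced spectrum; energy, slope and the log-log
# exponent on the raw Welch spectrum, preserving their physical scaling; LPC
# works on the raw waveform and MFCC on the raw power spectrum (the power-law
# compression has no defined waveform counterpart).

#' Extract the 40-parameter vector of an event
#'
#' For respiratory events (inhalation/exhalation) the parameters are computed
#' once per event from a Welch-averaged spectrum and the vector is returned
#' as a named numeric of length 40. For vowels every parameter is computed
#' frame-wise (one Hann frame per hop) and a 40 x n_frames matrix is
#' returned, to be aggregated over the phonation time. Undefined features
#' (silent frames, unvoiced frames, degenerate signals) are carried as `NA`,
#' never silent zeros.
#'
#' @param segment a `vb_segment` from [segment_events()].
#' @param cfg a [feature_config()].
#' @param rate_bpm repetition rate of the event's type (parameter 2 for
#'   respiratory events), from [event_rate_bpm()]; `NA` when unavailable.
#' @param mode `"event"` (one vector) or `"frames"` (per-frame matrix);
#'   defaults to `"frames"` for vowels and `"event"` otherwise.
#' @return A named numeric of length 40, or a 40-row matrix in frame mode.
#' @export
extract_parameter_vector <- function(segment, cfg = feature_config(),
                                     rate_bpm = NA_real_, mode = NULL) {
  stopifnot(inherits(segment, "vb_segment") || is.list(segment))
  if (is.null(mode))
    mode <- if (identical(segment$event_type, "vowel")) "frames" else "event"
  mode <- match.arg(mode, c("event", "frames"))
  ids <- parameter_table()$name

  if (mode == "event") {
    raw <- compute_spectrum(segment, cfg, mode = "welch")
    v <- c(segment$duration_s, rate_bpm,
           spectral_vector(raw, cfg),
           lpc_mfcc_vector(segment$samples, raw, cfg))
    return(setNames(v, ids))
  }

  frames <- compute_spectrum(segment, cfg, mode = "frames")
  x <- segment$samples
  rate <- segment$sample_rate_hz
  starts <- seq(1L, length(x) - cfg$frame_size + 1L, by = cfg$hop)
  f0_win <- max(cfg$frame_size, 3L * ceiling(rate / cfg$f0_band[1]))
  out <- vapply(seq_along(starts), function(i) {
    s <- starts[i]
    fr <- x[s:(s + cfg$frame_size - 1L)]
    f0_start <- min(s, max(1L, length(x) - f0_win + 1L))
    f0_chunk <- x[f0_start:min(length(x), f0_start + f0_win - 1L)]
    f0 <- na_if_undefined(fundamental_frequency(f0_chunk, rate,
                                                f0_band = cfg$f0_band))
    c(cfg$frame_size / rate, f0,
      spectral_vector(frames[[i]], cfg),
      lpc_mfcc_vector(fr, frames[[i]], cfg))
  }, numeric(40L))
  rownames(out) <- ids
  out
}

# Parameters 3-9 from one raw spectrum (enhancement applied internally).
spectral_vector <- function(raw, cfg) {
  enh <- enhance_resonances(raw, cfg$gamma)
  mom <- na_if_undefined(spectral_moments(enh))
  if (length(mom) == 1L && is.na(mom)) mom <- c(NA_real_, NA_real_)
  ef_raw <- na_if_undefined(energy_flatness(raw, floor = cfg$flatness_floor))
  flat <- na_if_undefined(energy_flatness(enh, floor = cfg$flatness_floor)[["flatness"]])
  energy <- if (length(ef_raw) == 1L && is.na(ef_raw)) NA_real_ else ef_raw[["energy"]]
  roll <- na_if_undefined(spectral_rolloff(enh, cfg$rolloff_fraction))
  sl <- na_if_undefined(spectral_slopes(raw))
  if (length(sl) == 1L && is.na(sl)) sl <- c(NA_real_, NA_real_)
  c(mom[1], mom[2], energy, flat, roll, sl[1], sl[2])
}

# Parameters 10-23 (LPC on the waveform) and 24-40 (MFCC on the raw power
# spectrum).
lpc_mfcc_vector <- function(samples, raw_spec, cfg) {
  lpc <- na_if_undefined(lpc_coefficients(samples, cfg$lpc_order))
  if (length(lpc) == 1L && is.na(lpc)) lpc <- rep(NA_real_, cfg$lpc_order)
  mf <- na_if_undefined(mfcc_from_spectrum(raw_spec, cfg$n_mfcc, cfg$n_mels))
  if (length(mf) == 1L && is.na(mf)) mf <- rep(NA_real_, cfg$n_mfcc)
  c(lpc, mf)
}

#' Aggregate parameter vectors into the 80 mu/sigma biomarkers
#'
#' For every parameter `n`, `mu_n` is the mean and `sigma_n` the population
#' standard deviation over the aggregation pool — the three repetitions for
#' respiratory events, the frames of the phonation time for vowels. Missing
#' values are excluded per parameter; a parameter with an empty pool yields
#' missing biomarkers. A single-member pool yields `sigma_n = 0`.
#'
#' @param vectors a 40-row matrix (one column per event/frame) or a list of
#'   named numeric vectors of length 40.
#' @param mode `"repetitions"` or `"frames"` (metadata only; the arithmetic
#'   is identical).
#' @return An object of class `vb_biomarkers`: list with numeric vectors
#'   `mu` and `sigma` (length 40 each, named `mu_1..mu_40`,
#'   `sigma_1..sigma_40`) and the `mode`.
#' @export
aggregate_biomarkers <- function(vectors, mode = c("repetitions", "frames")) {
  mode <- match.arg(mode)
  if (is.list(vectors) && !is.matrix(vectors))
    vectors <- do.call(cbind, vectors)
  if (!is.matrix(vectors) || nrow(vectors) != 40L)
    stop_validation("aggregate_biomarkers expects 40-parameter vectors")
  if (ncol(vectors) < 1L) stop_validation("aggregation pool is empty")
  mu <- apply(vectors, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  })
  sigma <- apply(vectors, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else sqrt(mean((v - mean(v))^2))
  })
  structure(list(mu = setNames(mu, paste0("mu_", 1:40)),
                 sigma = setNames(sigma, paste0("sigma_", 1:40)),
                 mode = mode),
            class = "vb_biomarkers")
}

#' @export
print.vb_biomarkers <- function(x, ...) {
  cat(sprintf("<vb_biomarkers> 80 biomarkers aggregated over %s (%d defined)\n",
              x$mode, sum(!is.na(c(x$mu, x$sigma)))))
  invisible(x)
}

#' Biomarkers of one sound type from its grouped segments
#'
#' Convenience wrapper tying together timing, per-event (or per-frame)
#' extraction and aggregation for the segments of a single sound type.
#' Respiratory events are aggregated over repetitions; vowels frame-wise
#' over the phonation time (multiple vowel segments contribute their frames
#' to one pool).
#'
#' @param segments ordered list of `vb_segment` of one event type.
#' @param cfg a [feature_config()].
#' @return A `vb_biomarkers` object.
#' @export
biomarkers_for_type <- function(segments, cfg = feature_config()) {
  if (!length(segments)) stop_validation("no segments for this sound type")
  type <- segments[[1]]$event_type
  if (type == "vowel") {
    mats <- lapply(segments, extract_parameter_vector, cfg = cfg)
    return(aggregate_biomarkers(do.call(cbind, mats), mode = "frames"))
  }
  rate <- na_if_undefined(event_rate_bpm(segments))
  vecs <- vapply(segments, extract_parameter_vector, numeric(40L),
                 cfg = cfg, rate_bpm = rate)
  aggregate_biomarkers(vecs, mode = "repetitions")
}
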