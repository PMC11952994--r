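#' Feature extraction configuration
#'
#' Frame/hop sizes, resonance-enhancement exponent and the knobs of the
#' Table-style 40-parameter set.
#'
#' @param frame_size analysis frame length in samples (Hann window).
#' @param hop hop size in samples (default 50\% overlap).
#' @param gamma resonance-enhancement exponent in (0, 1]; 1 disables
#'   enhancement.
#' @param rolloff_fraction cumulative-intensity fraction for the roll-off
#'   frequency (default 0.80).
#' @param lpc_order number of linear prediction coefficients (default 14).
#' @param n_mfcc number of mel-frequency cepstral coefficients, 0th excluded
#'   (default 17).
#' @param n_mels number of triangular mel filters spanning 0..Nyquist.
#' @param f0_band two-element search band in Hz for the vowel fundamental.
#' @param intensity `"power"` (squared magnitude, default) or `"magnitude"`.
#' @param flatness_floor relative floor (fraction of the spectral maximum)
#'   applied to zero bins before the geometric mean; 0 disables the floor.
#' @return A list of class `vb_feature_config`.
#' @export
feature_config <- function(frame_size = 2048L, hop = frame_size %/% 2L,
                           gamma = 0.5, rolloff_fraction = 0.80,
                           lpc_order = 14L, n_mfcc = 17L, n_mels = 26L,
                           f0_band = c(60, 400), intensity = c("power", "magnitude"),
                           flatness_floor = 1e-12) {
  intensity <- match.arg(intensity)
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must lie in (0, 1]")
  stopifnot(frame_size >= 16L, hop >= 1L, rolloff_fraction > 0,
            rolloff_fraction <= 1, length(f0_band) == 2L,
            f0_band[1] > 0, f0_band[2] > f0_band[1])
  structure(list(frame_size = as.integer(frame_size), hop = as.integer(hop),
                 gamma = gamma, rolloff_fraction = rolloff_fraction,
                 lpc_order = as.integer(lpc_order), n_mfcc = as.integer(n_mfcc),
                 n_mels = as.integer(n_mels), f0_band = f0_band,
                 intensity = intensity, flatness_floor = flatness_floor),
            class = "vb_feature_config")
}

#' Construct a spectrum object
#'
#' An intensity-frequency distribution: non-negative intensity per bin-center
#' frequency, bounded above by the Nyquist frequency.
#'
#' @param freqs_hz bin-center frequencies, non-decreasing.
#' @param intensity non-negative intensity per bin.
#' @param nyquist_hz Nyquist frequency (half the sampling rate).
#' @return An object of class `vb_spectrum`.
#' @export
spectrum_obj <- function(freqs_hz, intensity, nyquist_hz) {
  stopifnot(length(freqs_hz) == length(intensity), length(freqs_hz) >= 1L)
  if (any(intensity < 0)) stop_validation("spectrum intensity must be non-negative")
  if (max(freqs_hz) > nyquist_hz + 1e-9)
    stop_validation("spectrum bins must not exceed the Nyquist frequency")
  structure(list(freqs_hz = as.numeric(freqs_hz),
                 intensity = as.numeric(intensity),
                 nyquist_hz = as.numeric(nyquist_hz)),
            class = "vb_spectrum")
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

# One-sided intensity of a single windowed frame.
frame_intensity <- function(frame, window, intensity = "power") {
  n <- length(frame)
  mag <- Mod(fft(frame * window))[seq_len(n %/% 2L + 1L)]
  if (intensity == "power") mag^2 else mag
}

#' Compute the spectrum of an event segment
#'
#' The signal is Hann-windowed and Fourier-transformed; intensity is the
#' squared magnitude of the transform (configurable to plain magnitude).
#' In `"welch"` mode the periodograms of all overlapping frames are averaged
#' into a single event spectrum; in `"frames"` mode one spectrum per hop is
#' returned. Bins span 0..Nyquist, so a 44.1 kHz segment is bounded at
#' 22.05 kHz.
#'
#' @param segment a `vb_segment`, `vb_recording`, or numeric vector.
#' @param cfg a [feature_config()].
#' @param mode `"welch"` (one averaged spectrum) or `"frames"` (a list).
#' @param sample_rate_hz required when `segment` is a bare numeric vector.
#' @return A `vb_spectrum`, or a list of them in `"frames"` mode.
#' @export
compute_spectrum <- function(segment, cfg = feature_config(),
                             mode = c("welch", "frames"),
                             sample_rate_hz = NULL) {
  mode <- match.arg(mode)
  if (is.numeric(segment)) {
    if (is.null(sample_rate_hz)) stop("sample_rate_hz required for bare vectors")
    segment <- list(samples = as.numeric(segment), sample_rate_hz = sample_rate_hz)
  }
  x <- segment$samples
  rate <- segment$sample_rate_hz
  if (!length(x)) stop_validation("cannot compute the spectrum of an empty segment")
  nf <- cfg$frame_size
  if (length(x) < nf)
    stop_validation(sprintf("segment (%d samples) shorter than one %d-sample frame",
                            length(x), nf))
  window <- hann_window(nf)
  starts <- seq(1L, length(x) - nf + 1L, by = cfg$hop)
  freqs <- (seq_len(nf %/% 2L + 1L) - 1L) * rate / nf
  nyq <- rate / 2
  if (mode == "frames") {
    lapply(starts, function(s)
      spectrum_obj(freqs, frame_intensity(x[s:(s + nf - 1L)], window, cfg$intensity), nyq))
  } else {
    acc <- Reduce(`+`, lapply(starts, function(s)
      frame_intensity(x[s:(s + nf - 1L)], window, cfg$intensity)))
    spectrum_obj(freqs, acc / length(starts), nyq)
  }
}

#' Enhance resonant content of a spectrum
#'
#' Applies the per-bin power-law compression `S -> S^gamma` (gamma in
#' (0, 1]). Compression raises the weakest spectral components relative to the
#' strongest ones while preserving the rank order of bins, so resonances that
#' were attenuated on their way through the respiratory tract become
#' comparable to the dominant ones before shape features are measured.
#' `gamma = 1` is the identity.
#'
#' @param spec a `vb_spectrum`.
#' @param gamma compression exponent in (0, 1].
#' @return The compressed `vb_spectrum`.
#' @export
enhance_resonances <- function(spec, gamma = 0.5) {
  stopifnot(inherits(spec, "vb_spectrum"))
  if (!(is.numeric(gamma) && length(gamma) == 1L && gamma > 0 && gamma <= 1))
    stop("gamma must lie in (0, 1]")
  spectrum_obj(spec$freqs_hz, spec$intensity^gamma, spec$nyquist_hz)
}
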