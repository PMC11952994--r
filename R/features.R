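# The 40-parameter set: timing (1-2), spectral moments and shape (3-9),
# linear prediction (10-23), mel cepstrum (24-40).

#' Table of the 40 acoustic parameters
#'
#' @return A data frame with columns `id` and `name` describing every
#'   parameter of the per-event vector.
#' @export
parameter_table <- function() {
  data.frame(
    id = 1:40,
    name = c("duration_s", "rate_or_pitch",
             "spectral_centroid_hz", "spectral_spread_hz",
             "spectral_energy", "spectral_flatness",
             "spectral_rolloff80_hz", "spectral_slope", "spectral_exponent",
             paste0("lpc_", 1:14), paste0("mfcc_", 1:17)),
    stringsAsFactors = FALSE)
}

total_intensity_or_stop <- function(spec) {
  tot <- sum(spec$intensity)
  if (tot <= 0) stop_undefined_feature("zero total spectral intensity")
  tot
}

#' Spectral centroid and spread
#'
#' Centroid is the intensity-weighted mean frequency of the spectrum; spread
#' is the intensity-weighted standard deviation around it. Both lie in
#' \[0, Nyquist\].
#'
#' @param spec a `vb_spectrum` with positive total intensity.
#' @return Named numeric vector `c(centroid_hz, spread_hz)`.
#' @export
spectral_moments <- function(spec) {
  tot <- total_intensity_or_stop(spec)
  w <- spec$intensity / tot
  centroid <- sum(spec$freqs_hz * w)
  spread <- sqrt(sum((spec$freqs_hz - centroid)^2 * w))
  c(centroid_hz = centroid, spread_hz = spread)
}

#' Spectral energy and flatness
#'
#' Energy is the area of the intensity-frequency distribution (the summed bin
#' intensity). Flatness is the geometric-to-arithmetic mean ratio, in
#' \[0, 1\]: 1 for a flat (noise-like) spectrum, toward 0 for tonal spectra.
#' Bins below `floor` times the spectral maximum are floored there before the
#' geometric mean so silence padding cannot zero the statistic; `floor = 0`
#' disables this.
#'
#' @param spec a `vb_spectrum` with at least one bin.
#' @param floor relative floor for zero bins (fraction of the max intensity).
#' @return Named numeric vector `c(energy, flatness)`.
#' @export
energy_flatness <- function(spec, floor = 1e-12) {
  if (!length(spec$intensity)) stop_undefined_feature("empty spectrum")
  tot <- total_intensity_or_stop(spec)
  s <- spec$intensity
  s <- pmax(s, floor * max(s))
  am <- mean(s)
  gm <- if (any(s == 0)) 0 else exp(mean(log(s)))
  c(energy = tot, flatness = gm / am)
}

#' Spectral roll-off frequency
#'
#' The smallest bin frequency at which the cumulative intensity reaches
#' `fraction` of the total (default 80\%): a measure of how concentrated the
#' spectral content is in the low end.
#'
#' @param spec a `vb_spectrum` with positive total intensity.
#' @param fraction cumulative fraction in (0, 1].
#' @return Roll-off frequency in Hz.
#' @export
spectral_rolloff <- function(spec, fraction = 0.80) {
  stopifnot(fraction > 0, fraction <= 1)
  tot <- total_intensity_or_stop(spec)
  idx <- which(cumsum(spec$intensity) >= fraction * tot - 1e-12 * tot)[1]
  spec$freqs_hz[idx]
}

ls_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Spectral slope and exponent
#'
#' Slope is the least-squares slope of intensity against frequency (average
#' intensity decay/rise across frequency). Exponent is the least-squares
#' slope of log intensity against log frequency over bins with positive
#' intensity at positive frequency — the power-law exponent of the spectrum.
#'
#' @param spec a `vb_spectrum` with positive total intensity; the exponent
#'   needs at least two usable bins.
#' @return Named numeric vector `c(slope, exponent)`.
#' @export
spectral_slopes <- function(spec) {
  total_intensity_or_stop(spec)
  if (length(spec$freqs_hz) < 2L)
    stop_undefined_feature("need at least 2 bins for spectral slopes")
  slope <- ls_slope(spec$freqs_hz, spec$intensity)
  ok <- spec$intensity > 0 & spec$freqs_hz > 0
  if (sum(ok) < 2L)
    stop_undefined_feature("need at least 2 positive-intensity bins at positive frequency")
  exponent <- ls_slope(log(spec$freqs_hz[ok]), log(spec$intensity[ok]))
  c(slope = slope, exponent = exponent)
}

#' Linear prediction coefficients
#'
#' Autocorrelation-method LPC via the Levinson-Durbin recursion, returning
#' predictor coefficients `a_1..a_order` in the convention
#' `x^[n] = sum_k a_k x[n-k]`. The coefficients are a compact polynomial
#' description of the spectral envelope, compressing resonance locations and
#' widths. A small white-noise loading (`loading` times the lag-0
#' autocorrelation) keeps the normal equations well conditioned for strongly
#' band-limited signals.
#'
#' @param samples numeric waveform (or a `vb_segment`).
#' @param order prediction order (default 14).
#' @param loading relative diagonal loading of the lag-0 autocorrelation.
#' @return Numeric vector of `order` coefficients.
#' @export
lpc_coefficients <- function(samples, order = 14L, loading = 1e-9) {
  if (is.list(samples)) samples <- samples$samples
  order <- as.integer(order)
  n <- length(samples)
  if (n <= order)
    stop_undefined_feature("segment not longer than the LPC order")
  x <- as.numeric(samples)
  if (all(x == 0) || stats::var(x) == 0)
    stop_undefined_feature("degenerate (constant) signal for LPC")
  # biased autocorrelation (divisor n), no demeaning
  r <- vapply(0:order, function(k) sum(x[seq_len(n - k)] * x[(k + 1):n]) / n,
              numeric(1))
  r[1] <- r[1] * (1 + loading)
  a <- numeric(0)
  e <- r[1]
  for (i in seq_len(order)) {
    acc <- r[i + 1L] - if (i > 1L) sum(a * r[i:2]) else 0
    if (e <= 0) stop_undefined_feature("degenerate autocorrelation for LPC")
    k <- acc / e
    a <- c(a - k * rev(a), k)
    e <- e * (1 - k^2)
  }
  a
}

# HTK mel scale.
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank matrix
#'
#' `n_mels` triangular filters with peaks equally spaced on the HTK mel scale
#' between 0 Hz and the Nyquist frequency, evaluated at the given bin-center
#' frequencies.
#'
#' @param freqs_hz spectrum bin-center frequencies.
#' @param nyquist_hz Nyquist frequency.
#' @param n_mels number of filters.
#' @return An `n_mels` x `length(freqs_hz)` weight matrix.
#' @export
mel_filterbank <- function(freqs_hz, nyquist_hz, n_mels = 26L) {
  edges <- mel_to_hz(seq(0, hz_to_mel(nyquist_hz), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, length(freqs_hz))
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; mid <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (freqs_hz - lo) / (mid - lo)
    down <- (hi - freqs_hz) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mel-frequency cepstral coefficients of a power spectrum
#'
#' Applies a triangular mel filterbank to the power spectrum, takes the log
#' of the filter energies, and an orthonormal DCT-II; coefficients
#' `1..n_mfcc` are returned (the 0th, which carries overall level, is
#' excluded, making the coefficients invariant to uniform waveform scaling).
#'
#' @param spec a `vb_spectrum` (power intensity).
#' @param n_mfcc number of coefficients (default 17).
#' @param n_mels number of mel filters (default 26).
#' @return Numeric vector of `n_mfcc` coefficients.
#' @export
mfcc_from_spectrum <- function(spec, n_mfcc = 17L, n_mels = 26L) {
  stopifnot(inherits(spec, "vb_spectrum"), n_mfcc < n_mels)
  fb <- mel_filterbank(spec$freqs_hz, spec$nyquist_hz, n_mels)
  energies <- as.numeric(fb %*% spec$intensity)
  if (all(energies <= 0)) stop_undefined_feature("silent frame: zero mel energies")
  energies <- pmax(energies, 1e-30 * max(energies))
  loge <- log(energies)
  j <- seq_len(n_mfcc)
  m <- seq_len(n_mels)
  dct <- sqrt(2 / n_mels) * cos(outer(j, m - 0.5) * pi / n_mels)
  as.numeric(dct %*% loge)
}

#' @rdname mfcc_from_spectrum
#' @param samples numeric waveform (or `vb_segment`); a single Hann-windowed
#'   power spectrum of the whole input is used.
#' @param sample_rate_hz sampling rate for bare numeric input.
#' @param cfg a [feature_config()] (frame size is taken as the input length).
#' @export
mfcc_coefficients <- function(samples, sample_rate_hz = NULL,
                              cfg = feature_config()) {
  if (is.list(samples)) {
    sample_rate_hz <- samples$sample_rate_hz
    samples <- samples$samples
  }
  if (is.null(sample_rate_hz)) stop("sample_rate_hz required for bare vectors")
  n <- length(samples)
  spec <- spectrum_obj((seq_len(n %/% 2L + 1L) - 1L) * sample_rate_hz / n,
                       frame_intensity(samples, hann_window(n), "power"),
                       sample_rate_hz / 2)
  mfcc_from_spectrum(spec, cfg$n_mfcc, cfg$n_mels)
}

#' Fundamental frequency by autocorrelation
#'
#' Estimates the vocal-fold oscillation frequency of a voiced segment: the
#' normalised autocorrelation is searched for its maximum in the lag band
#' corresponding to `f0_band`, refined by parabolic interpolation. Segments
#' whose peak normalised autocorrelation falls below `voicing_threshold` are
#' reported unvoiced (an undefined-feature condition, skipped in
#' aggregation).
#'
#' @param samples numeric waveform (or `vb_segment`).
#' @param sample_rate_hz sampling rate for bare numeric input.
#' @param f0_band two-element search band in Hz (default 60-400).
#' @param voicing_threshold minimum normalised autocorrelation peak.
#' @return Estimated f0 in Hz.
#' @export
fundamental_frequency <- function(samples, sample_rate_hz = NULL,
                                  f0_band = c(60, 400),
                                  voicing_threshold = 0.3) {
  if (is.list(samples)) {
    sample_rate_hz <- samples$sample_rate_hz
    samples <- samples$samples
  }
  if (is.null(sample_rate_hz)) stop("sample_rate_hz required for bare vectors")
  n <- length(samples)
  min_lag <- max(2L, floor(sample_rate_hz / f0_band[2]))
  max_lag <- ceiling(sample_rate_hz / f0_band[1])
  if (n < 3L * max_lag)
    stop_undefined_feature("segment shorter than 3 periods of the lowest search frequency")
  x <- samples - mean(samples)
  if (all(x == 0)) stop_undefined_feature("silent segment: no periodicity")
  # autocorrelation via FFT (zero-padded to avoid circular wrap)
  nfft <- 2^ceiling(log2(2L * n))
  sp <- fft(c(x, numeric(nfft - n)))
  ac <- Re(fft(sp * Conj(sp), inverse = TRUE))[seq_len(max_lag + 2L)]
  ac <- ac / ac[1]
  lags <- min_lag:max_lag
  peak <- lags[which.max(ac[lags + 1L])]
  if (ac[peak + 1L] < voicing_threshold)
    stop_undefined_feature("no periodicity above the voicing threshold (unvoiced)")
  # octave correction: if an integer sub-multiple of the winning lag carries a
  # comparably strong peak, the winner was a period multiple - take the
  # smallest strong sub-multiple (searched over +/-1 lag for grid mismatch)
  k_max <- floor(peak / min_lag)
  for (k in (if (k_max >= 2L) seq.int(k_max, 2L) else integer())) {
    cand <- round(peak / k) + (-1L):1L
    cand <- cand[cand >= min_lag]
    if (!length(cand)) next
    cand <- cand[which.max(ac[cand + 1L])]
    if (ac[cand + 1L] >= 0.9 * ac[peak + 1L]) { peak <- cand; break }
  }
  # parabolic refinement around the integer-lag peak
  y1 <- ac[peak]; y2 <- ac[peak + 1L]; y3 <- ac[peak + 2L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  sample_rate_hz / (peak + delta)
}

#' Per-event duration and repetition rate
#'
#' Duration is the length of each event in seconds. The rate is the
#' occurrence frequency of the event type in beats per minute, computed as
#' 60 divided by the mean inter-onset interval of same-type events and
#' assigned to every event of the type; it needs at least two events.
#'
#' @param segments ordered list of `vb_segment` of one event type (with
#'   `start_s` onsets).
#' @return A data frame with one row per event and columns `duration_s`,
#'   `rate_bpm` (`rate_bpm` is `NA` when fewer than two events exist, in which
#'   case [event_rate_bpm()] raises an undefined-feature condition).
#' @export
event_timing <- function(segments) {
  if (!length(segments)) stop_validation("event_timing needs at least one segment")
  dur <- vapply(segments, function(s) s$duration_s, numeric(1))
  rate <- na_if_undefined(event_rate_bpm(segments))
  data.frame(duration_s = dur, rate_bpm = rate)
}

#' @rdname event_timing
#' @export
event_rate_bpm <- function(segments) {
  if (length(segments) < 2L)
    stop_undefined_feature("repetition rate needs at least two events of the type")
  onsets <- vapply(segments, function(s) s$start_s, numeric(1))
  60 / mean(diff(sort(onsets)))
}
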