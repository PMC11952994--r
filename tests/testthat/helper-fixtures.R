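# Fixtures built in code: tones, noise-burst recordings with labels, and a
# small fast synthesis configuration used by the pipeline tests.

sine_wave <- function(freq_hz, duration_s, rate = 44100, amp = 0.5) {
  amp * sin(2 * pi * freq_hz * (seq_len(round(duration_s * rate)) - 1L) / rate)
}

sawtooth_wave <- function(freq_hz, duration_s, rate = 44100, amp = 0.5) {
  t <- (seq_len(round(duration_s * rate)) - 1L) / rate
  amp * (2 * ((t * freq_hz) %% 1) - 1)
}

as_segment <- function(samples, rate, event_type = "exhalation", start_s = 0) {
  structure(list(samples = samples, sample_rate_hz = rate,
                 event_type = event_type,
                 duration_s = length(samples) / rate, start_s = start_s),
            class = "vb_segment")
}

# A recording with noise-burst events over a quiet background, plus its
# labels: the standard task layout (3 inhalations, 3 exhalations, 1 vowel).
burst_recording <- function(rate = 16000, event_amp = 0.3, floor_amp = 3e-4,
                            seed = 99L) {
  set.seed(seed)
  layout <- data.frame(
    event_type = rep(c("inhalation", "exhalation"), 3),
    start_s = c(0.3, 0.9, 1.5, 2.1, 2.7, 3.3),
    end_s = c(0.8, 1.4, 2.0, 2.6, 3.2, 3.8))
  layout <- rbind(layout, data.frame(event_type = "vowel", start_s = 4.0,
                                     end_s = 4.6))
  n <- round(5.0 * rate)
  x <- rnorm(n) * floor_amp
  for (i in seq_len(nrow(layout))) {
    idx <- (floor(layout$start_s[i] * rate) + 1L):floor(layout$end_s[i] * rate)
    x[idx] <- x[idx] + event_amp * rnorm(length(idx))
  }
  list(rec = recording(pmin(1, pmax(-1, x)), rate, subject_id = "T01"),
       labels = layout)
}

# Fast synthesis configuration for pipeline tests (16 kHz, short events).
fast_synth_cfg <- function(...) {
  synthesis_config(sample_rate_hz = 16000L, inh_duration_s = 0.5,
                   exh_duration_s = 0.8, vowel_duration_s = 0.9,
                   gap_s = 0.25, noise_band_hz = c(100, 5000),
                   exh_center_hz = 1200, exh_bw_hz = 300, ...)
}

# A random positive spectrum for oracle-equivalence loops.
random_spectrum <- function(n_bins = 64, nyquist = 8000) {
  freqs <- seq(0, nyquist, length.out = n_bins)
  spectrum_obj(freqs, stats::runif(n_bins, 0.01, 2), nyquist)
}
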