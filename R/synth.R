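# Seeded synthetic cohorts: Hill-type FEV1 dose-responses and source-filter
# audio whose resonant structure is coupled to the FEV1 ratio, so the whole
# extraction + correlation pipeline can be validated end-to-end.

#' Synthetic subject profile
#'
#' Describes one simulated subject: baseline lung function, latent airway
#' reactivity (the dose-response is Hill-type, calibrated so the noise-free
#' FEV1 fall is exactly 20\% at `latent_pd20_mcg`), and the acoustic coupling
#' that ties one synthesis control to the per-step FEV1 ratio.
#'
#' @param subject_id identifier string.
#' @param baseline_fev1_l baseline FEV1 in liters (> 0).
#' @param latent_pd20_mcg latent PD20 of the dose-response in mcg, or `NA`
#'   for a non-reactive subject (fall capped below 10\%).
#' @param hill_slope Hill exponent of the dose-response (default 2).
#' @param fmax_pct maximal FEV1 fall of a reactive subject (default 40\%;
#'   must exceed 20 so the latent PD20 is attainable).
#' @param coupling_target which synthesis control follows FEV1:
#'   `"resonance_center"` (exhalation resonance frequency, the default),
#'   `"spectral_tilt"` (exhalation noise tilt), or `"f0"` (vowel pitch).
#' @param coupling_gain gain of the coupling: Hz per unit fractional FEV1
#'   drop for `"resonance_center"`; tilt exponent per unit drop for
#'   `"spectral_tilt"`; fractional f0 rise per unit drop for `"f0"`.
#' @param noise_sd SD of additive Gaussian noise on measured FEV1 (liters);
#'   0 gives a noise-free dose-response.
#' @param seed integer seed fixing every draw for this subject.
#' @return A list of class `vb_subject_profile`.
#' @export
subject_profile <- function(subject_id = "S01", baseline_fev1_l = 3.40,
                            latent_pd20_mcg = NA_real_, hill_slope = 2,
                            fmax_pct = 40,
                            coupling_target = c("resonance_center",
                                                "spectral_tilt", "f0"),
                            coupling_gain = 1200, noise_sd = 0, seed = 1L) {
  coupling_target <- match.arg(coupling_target)
  stopifnot(baseline_fev1_l > 0, noise_sd >= 0, hill_slope > 0)
  if (!is.na(latent_pd20_mcg) && !(fmax_pct > 20 && latent_pd20_mcg > 0))
    stop("reactive profiles need fmax_pct > 20 and latent_pd20_mcg > 0")
  structure(list(subject_id = as.character(subject_id),
                 baseline_fev1_l = baseline_fev1_l,
                 latent_pd20_mcg = latent_pd20_mcg,
                 hill_slope = hill_slope, fmax_pct = fmax_pct,
                 coupling_target = coupling_target,
                 coupling_gain = coupling_gain,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "vb_subject_profile")
}

#' Audio synthesis configuration
#'
#' Durations, amplitudes and resonator settings of the synthetic respiratory
#' task: three cycles of deep inhalation and exhalation followed by a
#' sustained "A" vowel, recorded at a nominal smartphone rate of 44.1 kHz.
#'
#' @param sample_rate_hz sampling rate (default 44100).
#' @param inh_duration_s,exh_duration_s,vowel_duration_s event durations.
#' @param gap_s silence (noise floor only) between events.
#' @param exh_center_hz,exh_bw_hz exhalation resonance center and bandwidth
#'   at baseline FEV1.
#' @param inh_center_hz,inh_bw_hz inhalation resonance (uncoupled).
#' @param noise_band_hz band limits of the breath-noise excitation.
#' @param vowel_f0_hz vowel fundamental (60-400 Hz).
#' @param formants_hz,formant_bw_hz formant frequencies and bandwidths of the
#'   "A" vowel resonator cascade.
#' @param event_peak peak amplitude events are normalised to.
#' @param floor_amp amplitude of the background noise floor (about -80 dB
#'   full scale), present through the whole recording and drawn fresh for
#'   every recording.
#' @param excitation `"frozen"` (default): each subject re-uses the same
#'   breath-excitation noise realisation for repetition k of every step, so
#'   the FEV1 coupling is the dominant inter-step variation and the only
#'   fresh randomness is the recording noise floor; `"fresh"`: excitation is
#'   re-drawn per step, adding realistic attempt-to-attempt variability.
#' @return A list of class `vb_synthesis_config`.
#' @export
synthesis_config <- function(sample_rate_hz = 44100L,
                             inh_duration_s = 1.0, exh_duration_s = 1.5,
                             vowel_duration_s = 2.0, gap_s = 0.3,
                             exh_center_hz = 1400, exh_bw_hz = 400,
                             inh_center_hz = 900, inh_bw_hz = 600,
                             noise_band_hz = c(100, 6000),
                             vowel_f0_hz = 120,
                             formants_hz = c(800, 1200, 2600),
                             formant_bw_hz = c(80, 90, 120),
                             event_peak = 0.25, floor_amp = 1e-4,
                             excitation = c("frozen", "fresh")) {
  excitation <- match.arg(excitation)
  stopifnot(sample_rate_hz >= 8000, inh_duration_s > 0, exh_duration_s > 0,
            vowel_duration_s > 0, gap_s >= 0, event_peak > 0, event_peak <= 1,
            length(formants_hz) >= 2L,
            length(formant_bw_hz) == length(formants_hz))
  structure(as.list(environment()), class = "vb_synthesis_config")
}

# Two-pole resonator applied recursively; r set by the -3 dB bandwidth.
resonator <- function(x, center_hz, bw_hz, rate) {
  r <- exp(-pi * bw_hz / rate)
  theta <- 2 * pi * center_hz / rate
  as.numeric(stats::filter(x, c(2 * r * cos(theta), -r^2),
                           method = "recursive"))
}

# Band-limited (and optionally tilted) Gaussian noise via FFT masking.
bandlimited_noise <- function(n, rate, band_hz, tilt_exponent = 0) {
  x <- rnorm(n)
  spec <- fft(x)
  freqs <- (seq_len(n) - 1) * (rate / n)
  freqs <- pmin(freqs, rate - freqs)     # mirror for the upper half
  mask <- as.numeric(freqs >= band_hz[1] & freqs <= band_hz[2])
  if (tilt_exponent != 0)
    mask <- mask * ifelse(freqs > 0, (pmax(freqs, band_hz[1]) / band_hz[1])^(tilt_exponent / 2), 0)
  Re(fft(spec * mask, inverse = TRUE)) / n
}

raised_cosine_envelope <- function(n, rate, ramp_s = 0.05) {
  nr <- min(n %/% 2L, max(1L, round(ramp_s * rate)))
  env <- rep(1, n)
  ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 0.5) / nr)
  env[seq_len(nr)] <- ramp
  env[(n - nr + 1L):n] <- rev(ramp)
  env
}

peak_normalize <- function(x, peak) {
  m <- max(abs(x))
  if (m == 0) x else x * (peak / m)
}

#' Noise-free and noisy FEV1 dose-response
#'
#' Hill-type response: the FEV1 fall (percent of baseline) at cumulative dose
#' `d` is `Fmax d^h / (d^h + d50^h)`, with `d50` calibrated so the noise-free
#' fall is exactly 20\% at the profile's latent PD20 (for the default
#' `Fmax = 40`, `d50` equals the latent PD20). Non-reactive profiles use a
#' shallow response capped below a 10\% fall. Gaussian measurement noise
#' (`noise_sd`, liters) is added when nonzero, drawing from the current RNG
#' state.
#'
#' @param cumulative_dose_mcg cumulative dose, >= 0.
#' @param profile a [subject_profile()].
#' @return FEV1 in liters.
#' @export
fev1_response <- function(cumulative_dose_mcg, profile) {
  stopifnot(cumulative_dose_mcg >= 0)
  h <- profile$hill_slope
  if (is.na(profile$latent_pd20_mcg)) {
    fmax <- 8; d50 <- 800                # non-reactive: fall stays below 10%
  } else {
    fmax <- profile$fmax_pct
    d50 <- profile$latent_pd20_mcg * ((fmax - 20) / 20)^(1 / h)
  }
  d <- cumulative_dose_mcg
  fall <- if (d == 0) 0 else fmax * d^h / (d^h + d50^h)
  fev1 <- profile$baseline_fev1_l * (1 - fall / 100)
  if (profile$noise_sd > 0) fev1 <- fev1 + rnorm(1L, 0, profile$noise_sd)
  max(fev1, 0.1)
}

#' Synthesize one exhalation waveform
#'
#' Band-limited Gaussian noise passed through a single two-pole resonator
#' whose center frequency rises linearly with the fractional FEV1 drop:
#' `center = exh_center_hz + gain_hz * (1 - fev1_ratio)`, emulating the
#' upward shift of breath-sound resonances with airway narrowing. A smooth
#' raised-cosine onset/offset envelope is applied and the waveform is
#' peak-normalised. Deterministic for a given seed.
#'
#' @param fev1_ratio current FEV1 over baseline, in (0, 1.2].
#' @param cfg a [synthesis_config()].
#' @param seed integer seed.
#' @param gain_hz resonance-center coupling gain (Hz per unit drop).
#' @param tilt_exponent spectral tilt exponent of the excitation noise
#'   (0 = flat; used by the `"spectral_tilt"` coupling).
#' @return Numeric waveform.
#' @export
synth_exhalation <- function(fev1_ratio, cfg = synthesis_config(), seed = 1L,
                             gain_hz = 0, tilt_exponent = 0) {
  if (!(is.finite(fev1_ratio) && fev1_ratio > 0 && fev1_ratio <= 1.2))
    stop("fev1_ratio must lie in (0, 1.2]")
  set.seed(as.integer(seed))
  n <- round(cfg$exh_duration_s * cfg$sample_rate_hz)
  center <- cfg$exh_center_hz + gain_hz * (1 - fev1_ratio)
  x <- bandlimited_noise(n, cfg$sample_rate_hz, cfg$noise_band_hz, tilt_exponent)
  x <- resonator(x, center, cfg$exh_bw_hz, cfg$sample_rate_hz)
  x <- x * raised_cosine_envelope(n, cfg$sample_rate_hz)
  peak_normalize(x, cfg$event_peak)
}

#' Synthesize one inhalation waveform
#'
#' As [synth_exhalation()] but through the (uncoupled) inhalation resonator.
#'
#' @inheritParams synth_exhalation
#' @return Numeric waveform.
#' @export
synth_inhalation <- function(cfg = synthesis_config(), seed = 1L) {
  set.seed(as.integer(seed))
  n <- round(cfg$inh_duration_s * cfg$sample_rate_hz)
  x <- bandlimited_noise(n, cfg$sample_rate_hz, cfg$noise_band_hz)
  x <- resonator(x, cfg$inh_center_hz, cfg$inh_bw_hz, cfg$sample_rate_hz)
  x <- x * raised_cosine_envelope(n, cfg$sample_rate_hz)
  peak_normalize(x, cfg$event_peak)
}

#' Synthesize a sustained vowel
#'
#' Source-filter synthesis of an "A": a glottal impulse train at `f0_hz`
#' (pulses placed at the nearest sample to each period boundary, so the mean
#' period is exact) filtered by a cascade of two-pole formant resonators,
#' with a small aspiration-noise component, enveloped and peak-normalised.
#' The fundamental is recoverable by [fundamental_frequency()].
#'
#' @param f0_hz fundamental frequency in 60-400 Hz.
#' @param formants_hz,formant_bw_hz formant frequencies/bandwidths (>= 2
#'   formants).
#' @param duration_s vowel duration in seconds.
#' @param cfg a [synthesis_config()] (rate and amplitude).
#' @param seed integer seed.
#' @return Numeric waveform.
#' @export
synth_vowel <- function(f0_hz = 120, formants_hz = c(800, 1200, 2600),
                        formant_bw_hz = c(80, 90, 120), duration_s = 2.0,
                        cfg = synthesis_config(), seed = 1L) {
  if (!(f0_hz >= 60 && f0_hz <= 400))
    stop("f0_hz must lie in the 60-400 Hz search band")
  if (length(formants_hz) < 2L) stop("need at least 2 formants")
  set.seed(as.integer(seed))
  rate <- cfg$sample_rate_hz
  n <- round(duration_s * rate)
  src <- numeric(n)
  pulse_times <- seq(0, n - 1L, by = rate / f0_hz)
  src[round(pulse_times) + 1L] <- 1
  src <- src + 1e-3 * rnorm(n)           # aspiration noise
  for (k in seq_along(formants_hz))
    src <- resonator(src, formants_hz[k], formant_bw_hz[k], rate)
  src <- src * raised_cosine_envelope(n, rate)
  peak_normalize(src, cfg$event_peak)
}

# Deterministic sub-seed derivation (kept below 2^31 - 1).
derive_seed <- function(seed, ...) {
  k <- as.numeric(seed)
  for (i in c(...)) k <- (k * 69069 + 12345 + as.numeric(i)) %% 2147483647
  as.integer(k)
}

#' Simulate one subject's full MCT session
#'
#' Runs the challenge protocol on the profile's dose-response, and for every
#' executed step emits one recording containing the full respiratory task
#' (three inhalation/exhalation cycles, then a sustained vowel) with exact
#' event labels. The exhalation resonance (or tilt/f0, per the profile's
#' coupling target) is driven by that step's FEV1/baseline ratio. An
#' optional salbutamol-recovery step moves FEV1 back toward baseline.
#'
#' @param profile a [subject_profile()].
#' @param mct_cfg a [mct_config()].
#' @param synth_cfg a [synthesis_config()].
#' @param recovery_step add a post-challenge recovery step (FEV1 returns 75\%
#'   of the way to baseline)?
#' @return A list of class `vb_session` with `profile`, `outcome`
#'   (`vb_mct_outcome`), `session` (data frame: `subject_id`, `step_index`,
#'   `cumulative_dose_mcg`, `fev1_l`), `recordings` (named list of
#'   [recording()]s keyed by recording id) and `labels` (data frame with
#'   `recording_id`).
#' @export
simulate_session <- function(profile, mct_cfg = mct_config(),
                             synth_cfg = synthesis_config(),
                             recovery_step = FALSE) {
  stopifnot(inherits(profile, "vb_subject_profile"))
  set.seed(profile$seed)
  outcome <- run_protocol(function(d) fev1_response(d, profile), mct_cfg,
                          baseline_fev1_l = profile$baseline_fev1_l)
  steps <- outcome$steps
  if (recovery_step) {
    last <- steps[nrow(steps), ]
    rec_fev1 <- last$fev1_l + 0.75 * (outcome$baseline_fev1_l - last$fev1_l)
    steps[nrow(steps) + 1L, ] <- list(last$step_index + 1L,
                                      last$cumulative_dose_mcg, rec_fev1,
                                      100 * (outcome$baseline_fev1_l - rec_fev1) /
                                        outcome$baseline_fev1_l)
  }
  recordings <- list()
  labels <- NULL
  for (i in seq_len(nrow(steps))) {
    ratio <- min(1.2, steps$fev1_l[i] / outcome$baseline_fev1_l)
    rl <- synth_step_recording(profile, ratio, synth_cfg,
                               derive_seed(profile$seed, steps$step_index[i]),
                               subject_seed = profile$seed)
    rec_id <- sprintf("%s_step%02d", profile$subject_id, steps$step_index[i])
    recordings[[rec_id]] <- recording(rl$samples, synth_cfg$sample_rate_hz,
                                      subject_id = profile$subject_id,
                                      step_index = steps$step_index[i],
                                      task_id = rec_id)
    labels <- rbind(labels, cbind(recording_id = rec_id, rl$labels))
  }
  structure(list(profile = profile, outcome = outcome,
                 session = data.frame(subject_id = profile$subject_id,
                                      step_index = steps$step_index,
                                      cumulative_dose_mcg = steps$cumulative_dose_mcg,
                                      fev1_l = steps$fev1_l),
                 recordings = recordings, labels = labels),
            class = "vb_session")
}

# One step's recording: floor noise + 3 x (inhalation, exhalation) + vowel.
# Under frozen excitation the event seeds depend only on the subject (and
# repetition), not the step; the floor noise is always fresh per step.
synth_step_recording <- function(profile, ratio, cfg, seed,
                                 subject_seed = seed) {
  ev_seed <- if (identical(cfg$excitation, "frozen")) subject_seed else seed
  rate <- cfg$sample_rate_hz
  gain_hz <- if (profile$coupling_target == "resonance_center")
    profile$coupling_gain else 0
  tilt <- if (profile$coupling_target == "spectral_tilt")
    profile$coupling_gain * (1 - ratio) else 0
  f0 <- if (profile$coupling_target == "f0")
    cfg$vowel_f0_hz * (1 + profile$coupling_gain * (1 - ratio)) else
      cfg$vowel_f0_hz
  f0 <- min(400, max(60, f0))

  events <- list()
  for (cyc in 1:3) {
    events[[length(events) + 1L]] <-
      list(type = "inhalation",
           wave = synth_inhalation(cfg, derive_seed(ev_seed, 10L + cyc)))
    events[[length(events) + 1L]] <-
      list(type = "exhalation",
           wave = synth_exhalation(ratio, cfg, derive_seed(ev_seed, 20L + cyc),
                                   gain_hz = gain_hz, tilt_exponent = tilt))
  }
  events[[length(events) + 1L]] <-
    list(type = "vowel",
         wave = synth_vowel(f0, cfg$formants_hz, cfg$formant_bw_hz,
                            cfg$vowel_duration_s, cfg, derive_seed(ev_seed, 30L)))

  gap_n <- round(cfg$gap_s * rate)
  total_n <- gap_n + sum(vapply(events, function(e) length(e$wave) + gap_n,
                                numeric(1)))
  set.seed(derive_seed(seed, 99L))
  samples <- rnorm(total_n) * cfg$floor_amp
  pos <- gap_n
  labs <- data.frame(event_type = character(), start_s = numeric(),
                     end_s = numeric())
  for (e in events) {
    idx <- (pos + 1L):(pos + length(e$wave))
    samples[idx] <- samples[idx] + e$wave
    labs[nrow(labs) + 1L, ] <- list(e$type, pos / rate,
                                    (pos + length(e$wave)) / rate)
    pos <- pos + length(e$wave) + gap_n
  }
  list(samples = pmin(1, pmax(-1, samples)), labels = labs)
}

#' Simulate a cohort of subjects
#'
#' Draws subject profiles emulating a realistic adult MCT-referral cohort —
#' baseline FEV1
#' around Normal(3.40, 0.79) truncated above 1 L, a chosen fraction of
#' reactive subjects with latent PD20 around Normal(530.77, 264.24)
#' truncated to \[25, 800\] mcg — and simulates every session. Per-subject
#' seeds are derived from the master seed, so identical seeds give
#' bit-identical cohorts.
#'
#' @param n_subjects number of subjects (>= 1); ignored when `profiles` is
#'   given.
#' @param fraction_reactive fraction with a positive-range latent PD20.
#' @param seed master seed.
#' @param profiles optional list of [subject_profile()]s overriding the
#'   draws (then only sessions are simulated).
#' @param coupling_target,coupling_gain,noise_sd passed to every profile.
#' @param mct_cfg,synth_cfg protocol and synthesis configuration.
#' @param recovery_step add recovery steps (see [simulate_session()]).
#' @param profiles_only return the drawn profiles without synthesizing any
#'   session (cheap inspection of the cohort shape).
#' @return A list of class `vb_cohort` of `vb_session` objects, named by
#'   subject id (or a list of profiles when `profiles_only`).
#' @export
simulate_cohort <- function(n_subjects = NULL, fraction_reactive = 0.325,
                            seed = 1L, profiles = NULL,
                            coupling_target = "resonance_center",
                            coupling_gain = 1200, noise_sd = 0,
                            mct_cfg = mct_config(),
                            synth_cfg = synthesis_config(),
                            recovery_step = FALSE, profiles_only = FALSE) {
  if (is.null(profiles)) {
    stopifnot(!is.null(n_subjects), n_subjects >= 1,
              fraction_reactive >= 0, fraction_reactive <= 1)
    set.seed(as.integer(seed))
    n_reactive <- round(n_subjects * fraction_reactive)
    reactive <- sample(rep(c(TRUE, FALSE),
                           c(n_reactive, n_subjects - n_reactive)))
    baselines <- vapply(seq_len(n_subjects), function(i) {
      repeat { b <- rnorm(1, 3.40, 0.79); if (b > 1) return(b) }
    }, numeric(1))
    pd20s <- vapply(seq_len(n_subjects), function(i) {
      if (!reactive[i]) return(NA_real_)
      repeat { p <- rnorm(1, 530.77, 264.24); if (p >= 25 && p <= 800) return(p) }
    }, numeric(1))
    profiles <- lapply(seq_len(n_subjects), function(i)
      subject_profile(subject_id = sprintf("S%02d", i),
                      baseline_fev1_l = baselines[i],
                      latent_pd20_mcg = pd20s[i],
                      coupling_target = coupling_target,
                      coupling_gain = coupling_gain, noise_sd = noise_sd,
                      seed = derive_seed(seed, i)))
  }
  if (profiles_only) return(profiles)
  sessions <- lapply(profiles, simulate_session, mct_cfg = mct_cfg,
                     synth_cfg = synth_cfg, recovery_step = recovery_step)
  names(sessions) <- vapply(sessions, function(s) s$profile$subject_id,
                            character(1))
  structure(sessions, class = "vb_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the on-disk layout the extraction pipeline reads back: one WAV per
#' (subject, step) under `audio/`, a single `labels.tsv`, and `sessions.csv`.
#'
#' @param cohort a `vb_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "audio"), recursive = TRUE, showWarnings = FALSE)
  all_labels <- NULL
  all_sessions <- NULL
  for (s in cohort) {
    for (rec_id in names(s$recordings))
      write_wav(s$recordings[[rec_id]],
                file.path(dir, "audio", paste0(rec_id, ".wav")))
    all_labels <- rbind(all_labels, s$labels)
    all_sessions <- rbind(all_sessions, s$session)
  }
  write_labels(all_labels, file.path(dir, "labels.tsv"))
  write_session_table(all_sessions, file.path(dir, "sessions.csv"))
  invisible(dir)
}
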