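# Spectral descriptors against brute-force oracles and closed-form cases.

test_that("spectral moments match hand-computed and brute-force values", {
  single <- spectrum_obj(c(100, 440, 900), c(0, 3.2, 0), 8000)
  expect_equal(spectral_moments(single), c(centroid_hz = 440, spread_hz = 0))

  two <- spectrum_obj(c(100, 300), c(1, 1), 8000)
  expect_equal(spectral_moments(two), c(centroid_hz = 200, spread_hz = 100))

  set.seed(11)
  for (i in 1:100) {
    sp <- random_spectrum()
    got <- spectral_moments(sp)
    cen <- sum(sp$freqs_hz * sp$intensity) / sum(sp$intensity)
    spr <- sqrt(sum((sp$freqs_hz - cen)^2 * sp$intensity) / sum(sp$intensity))
    expect_equal(unname(got), c(cen, spr), tolerance = 1e-9)
  }
  expect_error(spectral_moments(spectrum_obj(1:4, rep(0, 4), 8000)),
               class = "vocalmct_undefined_feature")
})

test_that("energy and flatness match their definitions", {
  flat <- spectrum_obj(1:8, rep(3, 8), 8)
  expect_equal(unname(energy_flatness(flat)), c(24, 1))

  two <- spectrum_obj(c(1, 2), c(1, 4), 8)
  expect_equal(unname(energy_flatness(two)), c(5, 2 / 2.5))

  spike <- spectrum_obj(1:10, c(rep(0, 9), 5), 10)
  expect_equal(unname(energy_flatness(spike, floor = 0))[2], 0)

  set.seed(12)
  for (i in 1:100) {
    sp <- random_spectrum(32)
    got <- energy_flatness(sp, floor = 0)
    expect_equal(unname(got),
                 c(sum(sp$intensity),
                   prod(sp$intensity)^(1 / 32) / mean(sp$intensity)),
                 tolerance = 1e-9)
  }
  expect_error(energy_flatness(spectrum_obj(1:4, rep(0, 4), 8)),
               class = "vocalmct_undefined_feature")
})

test_that("roll-off returns the smallest bin reaching the cumulative fraction", {
  one <- spectrum_obj(777, 2, 8000)
  for (f in c(0.1, 0.8, 1)) expect_equal(spectral_rolloff(one, f), 777)

  flat10 <- spectrum_obj(seq(100, 1000, by = 100), rep(1, 10), 8000)
  expect_equal(spectral_rolloff(flat10, 0.8), 800)
  expect_equal(spectral_rolloff(flat10, 1), 1000)

  trailing <- spectrum_obj(1:10, c(rep(1, 6), rep(0, 4)), 10)
  expect_equal(spectral_rolloff(trailing, 1), 6)

  set.seed(13)
  for (i in 1:100) {
    sp <- random_spectrum(48)
    frac <- stats::runif(1, 0.05, 1)
    cum <- cumsum(sp$intensity) / sum(sp$intensity)
    expect_equal(spectral_rolloff(sp, frac),
                 sp$freqs_hz[which(cum >= frac - 1e-12)[1]])
  }
})

test_that("spectral slope and exponent match least-squares oracles", {
  flat <- spectrum_obj(seq(100, 1000, by = 100), rep(2, 10), 8000)
  expect_equal(unname(spectral_slopes(flat)), c(0, 0), tolerance = 1e-12)

  f <- seq(50, 4000, length.out = 40)
  inv <- spectrum_obj(f, 300 / f, 8000)
  expect_equal(unname(spectral_slopes(inv))[2], -1, tolerance = 1e-9)

  lin <- spectrum_obj(f, 0.4 + 0.002 * f, 8000)
  expect_equal(unname(spectral_slopes(lin))[1], 0.002, tolerance = 1e-9)

  set.seed(14)
  for (i in 1:100) {
    sp <- random_spectrum(32)
    got <- spectral_slopes(sp)
    fit1 <- stats::lm(sp$intensity ~ sp$freqs_hz)
    fit2 <- stats::lm(log(sp$intensity[-1]) ~ log(sp$freqs_hz[-1]))
    expect_equal(unname(got[1]), unname(stats::coef(fit1)[2]), tolerance = 1e-9)
    expect_equal(unname(got[2]), unname(stats::coef(fit2)[2]), tolerance = 1e-9)
  }
})

test_that("LPC recovers AR structure and matches an explicit Toeplitz solve", {
  set.seed(15)
  ar1 <- as.numeric(stats::arima.sim(list(ar = 0.9), n = 50000))
  a <- lpc_coefficients(ar1, 14)
  expect_length(a, 14L)
  expect_equal(a[1], 0.9, tolerance = 0.05)
  expect_lt(max(abs(a[2:14])), 0.05)

  white <- stats::rnorm(50000)
  expect_lt(max(abs(lpc_coefficients(white, 14))), 0.03)

  # oracle: Yule-Walker normal equations solved by explicit matrix inversion
  for (i in 1:100) {
    x <- stats::rnorm(512)
    p <- sample(2:14, 1)
    r <- vapply(0:p, function(k)
      sum(x[seq_len(512 - k)] * x[(k + 1):512]) / 512, numeric(1))
    r[1] <- r[1] * (1 + 1e-9)
    oracle <- solve(stats::toeplitz(r[1:p]), r[2:(p + 1)])
    expect_equal(lpc_coefficients(x, p), oracle, tolerance = 1e-9)
  }
  expect_error(lpc_coefficients(numeric(100), 14),
               class = "vocalmct_undefined_feature")
  expect_error(lpc_coefficients(stats::rnorm(10), 14),
               class = "vocalmct_undefined_feature")
})

test_that("MFCC matches an explicit filterbank-log-DCT composition", {
  set.seed(16)
  x <- stats::rnorm(1024)
  got <- mfcc_coefficients(x, sample_rate_hz = 16000)
  expect_length(got, 17L)

  # independent oracle assembled from first principles
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  n_mels <- 26L
  freqs <- (0:512) * 16000 / 1024
  w <- 0.5 - 0.5 * cos(2 * pi * (0:1023) / 1023)
  pow <- Mod(stats::fft(x * w))[1:513]^2
  pts <- imel(seq(0, mel(8000), length.out = n_mels + 2L))
  E <- numeric(n_mels)
  for (m in 1:n_mels) {
    weight <- pmax(0, pmin((freqs - pts[m]) / (pts[m + 1] - pts[m]),
                           (pts[m + 2] - freqs) / (pts[m + 2] - pts[m + 1])))
    E[m] <- sum(weight * pow)
  }
  oracle <- vapply(1:17, function(j)
    sqrt(2 / n_mels) * sum(log(pmax(E, 1e-30 * max(E))) *
                             cos(pi * j * ((1:n_mels) - 0.5) / n_mels)),
    numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)

  for (i in 1:100) {
    y <- stats::rnorm(256)
    sp <- compute_spectrum(y, feature_config(frame_size = 256L),
                           sample_rate_hz = 8000)
    a <- mfcc_from_spectrum(sp, 12, 20)
    fb <- mel_filterbank(sp$freqs_hz, 4000, 20)
    Ey <- as.numeric(fb %*% sp$intensity)
    oy <- vapply(1:12, function(j)
      sqrt(2 / 20) * sum(log(pmax(Ey, 1e-30 * max(Ey))) *
                           cos(pi * j * ((1:20) - 0.5) / 20)), numeric(1))
    expect_equal(a, oy, tolerance = 1e-9)
  }
  expect_error(mfcc_coefficients(numeric(1024), sample_rate_hz = 16000),
               class = "vocalmct_undefined_feature")
})

test_that("MFCC is invariant to uniform waveform scaling", {
  set.seed(17)
  x <- stats::rnorm(2048)
  base <- mfcc_coefficients(x, 16000)
  for (k in c(0.01, 3.7, 500))
    expect_equal(mfcc_coefficients(k * x, 16000), base, tolerance = 1e-8)
})

test_that("fundamental frequency is recovered for periodic signals", {
  saw <- sawtooth_wave(220, 0.5)
  expect_equal(fundamental_frequency(saw, 44100), 220, tolerance = 1 / 220)

  sine <- sine_wave(210, 0.5)
  expect_equal(fundamental_frequency(sine, 44100), 210, tolerance = 1 / 210)

  set.seed(18)
  expect_error(fundamental_frequency(stats::rnorm(22050), 44100),
               class = "vocalmct_undefined_feature")
  expect_error(fundamental_frequency(sine_wave(210, 0.02), 44100),
               class = "vocalmct_undefined_feature")
})

test_that("event timing gives per-event durations and a common rate", {
  segs <- list(as_segment(numeric(24000), 16000, start_s = 0.5))
  segs[[1]]$duration_s <- 1.5
  t1 <- event_timing(segs)
  expect_equal(t1$duration_s, 1.5)
  expect_true(is.na(t1$rate_bpm))
  expect_error(event_rate_bpm(segs), class = "vocalmct_undefined_feature")

  three <- lapply(c(0, 4, 8), function(s) as_segment(numeric(8000), 16000,
                                                     start_s = s))
  expect_equal(event_timing(three)$rate_bpm, rep(15, 3))
})
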