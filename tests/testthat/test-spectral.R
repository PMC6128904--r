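test_that("Welch PSD localizes pure tones and resolves nearby peaks", {
  fs <- 1000
  x <- sine(8, 30, fs)
  psd <- compute_psd(x, fs)
  expect_equal(psd$freqs[which.max(psd$power)], 8)
  # two tones 2 Hz apart resolve into two local maxima
  y <- sine(7, 60, fs) + sine(9, 60, fs)
  psd2 <- compute_psd(y, fs)
  pk <- detect_theta_peaks(psd2)
  expect_equal(pk$freq, c(7, 9), tolerance = 1e-3)
  expect_error(compute_psd(x[1:100], fs), "shorter")
})

test_that("raw PSD integral matches signal variance (Parseval consistency)", {
  set.seed(1)
  fs <- 1000
  x <- stats::rnorm(100 * fs)
  psd <- compute_psd(x, fs)
  total <- trapz_freqs <- sum(diff(psd$freqs) *
                              (psd$power[-1] + psd$power[-length(psd$power)]) / 2)
  expect_equal(total, stats::var(x), tolerance = 0.05)
})

test_that("white-noise spectra are flat after smoothing", {
  set.seed(2)
  fs <- 1000
  psd <- compute_psd(stats::rnorm(100 * fs), fs)
  sel <- psd$freqs >= 1 & psd$freqs <= 100
  # 0.5 Hz boxcar smoothing (3 bins at 1/3 Hz resolution)
  sm <- stats::filter(psd$power[sel], rep(1 / 3, 3))
  sm <- sm[!is.na(sm)]
  expect_lt(max(sm) / min(sm), 2)
})

test_that("baseline normalization is self-consistent and linear", {
  fs <- 1000
  base <- compute_psd(sine(7, 60, fs) + 0.1 * sine(3, 60, fs), fs)
  selfn <- normalize_psd(base, base)
  sel <- selfn$freqs >= 0 & selfn$freqs <= 14
  integral <- sum(diff(selfn$freqs[sel]) *
                  (selfn$power[sel][-1] + selfn$power[sel][-sum(sel)]) / 2)
  expect_equal(integral, 1, tolerance = 1e-9)
  # doubled power in the stim spectrum doubles normalized band power exactly
  stim <- base; stim$power <- 2 * base$power
  n_base <- normalize_psd(base, base)
  n_stim <- normalize_psd(stim, base)
  b <- band_definition("theta2", 6, 8)
  expect_equal(band_power(n_stim, b) / band_power(n_base, b), 2)
  # mismatched grids rejected
  other <- compute_psd(sine(7, 60, fs), fs, window_length = 2, overlap = 1)
  expect_error(normalize_psd(base, other), "grid")
})

test_that("band power integrates correctly and is additive", {
  psd <- as_flat <- structure(
    list(freqs = seq(0, 100, by = 0.5), power = rep(1, 201),
         normalization = "raw", window_length = 2, overlap = 0,
         n_segments = 1), class = "power_spectrum")
  expect_equal(band_power(psd, c(6, 8)), 2)
  expect_equal(band_power(psd, c(6, 7.25)) + band_power(psd, c(7.25, 8)),
               band_power(psd, c(6, 8)))
  expect_error(band_power(psd, c(90, 110)), "outside")
  # a pure 7 Hz tone concentrates its power in the 6-7.5 Hz band
  fs <- 1000
  tone <- compute_psd(sine(7, 60, fs), fs)
  expect_gt(band_power(tone, c(6, 7.5)) / band_power(tone, c(1, 100)), 0.95)
})

test_that("theta-peak detection ignores flat and 1/f-only spectra", {
  flat <- structure(
    list(freqs = seq(0.5, 50, by = 0.5), power = rep(1, 100),
         normalization = "raw", window_length = 2, overlap = 0,
         n_segments = 1), class = "power_spectrum")
  expect_equal(nrow(detect_theta_peaks(flat)), 0)
  set.seed(3)
  noise <- generate_session(single_osc_config(8, amplitude = 0, noise = 0.3,
                                              duration = 60, seed = 3))
  psd <- compute_psd(noise$lfp[1, ], 1000)
  expect_equal(nrow(detect_theta_peaks(psd)), 0)
})

test_that("spectrogram tracks a chirp and matches the single-window periodogram", {
  fs <- 1000
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  # linear chirp 5 -> 10 Hz
  f_inst <- 5 + (10 - 5) * t / 60
  x <- cos(2 * pi * cumsum(f_inst) / fs)
  sg <- spectrogram(x, fs, window_length = 3, step = 1)
  sel <- sg$freqs >= 2 & sg$freqs <= 15
  ridge <- sg$freqs[sel][apply(sg$power[sel, ], 2, which.max)]
  expect_true(all(diff(ridge) >= 0))
  # stationary tone: constant ridge
  sg2 <- spectrogram(sine(8, 30, fs), fs)
  ridge2 <- sg2$freqs[apply(sg2$power, 2, which.max)]
  expect_true(all(ridge2 == 8))
  # column t equals the periodogram of that window (oracle: direct transform)
  col5 <- sg2$power[, 5]
  s0 <- round(sg2$t[5] * fs) + 1
  direct <- compute_psd(sine(8, 30, fs)[s0:(s0 + 3 * fs - 1)], fs,
                        window_length = 3, overlap = 0)
  expect_equal(col5, direct$power, tolerance = 1e-12)
})
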