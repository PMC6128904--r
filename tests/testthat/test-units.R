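test_that("inserted spike templates are detected at the right times", {
  set.seed(1)
  fs <- 25000
  dur <- 10
  noise <- stats::rnorm(dur * fs, 0, 5)
  filt_sd <- stats::median(abs(bandpass(noise, fs, 500, 5000))) / 0.6745
  # template scaled so its trough is 8x the filtered-noise SD; with a 5 SD
  # threshold the expected Gaussian noise-crossing count is essentially 0
  tmpl <- as.numeric(make_spike_template(0.23, 1.4, fs = fs))
  tmpl <- tmpl * (8 * filt_sd / abs(min(tmpl)))
  insert_at <- round(seq(0.5, 9.5, by = 1) * fs)
  x <- noise
  for (i0 in insert_at) {
    idx <- i0 + seq_along(tmpl) - 1
    x[idx] <- x[idx] + tmpl
  }
  det <- detect_spikes(x, fs, threshold_sd = 5)
  true_troughs <- (insert_at + which.min(tmpl) - 2) / fs
  expect_equal(length(det$times), 10)
  expect_lt(max(abs(det$times - true_troughs)), 2e-4)
  # pure noise at a high threshold yields (almost) no detections
  det0 <- detect_spikes(noise, fs, threshold_sd = 6)
  expect_lte(length(det0$times), 1)
  # empty input
  det_e <- detect_spikes(numeric(0), fs)
  expect_length(det_e$times, 0)
  expect_error(detect_spikes(noise, 5000), "10 kHz")
})

test_that("waveform features invert the template generator across a parameter grid", {
  for (hw in c(0.2, 0.23, 0.36, 0.5)) {
    for (ratio in c(1.4, 3, 12.3)) {
      w <- make_spike_template(hw, ratio)
      f <- waveform_features(w)
      expect_equal(f$half_width, hw, tolerance = 0.01 / hw)
      expect_equal(f$peak_trough_ratio, ratio, tolerance = 0.02)
    }
  }
  # symmetric biphasic template: ratio 1
  f1 <- waveform_features(make_spike_template(0.3, 1))
  expect_equal(f1$peak_trough_ratio, 1, tolerance = 0.01)
  expect_error(waveform_features(structure(1:10 / 10, fs = 25000)), "trough")
})

test_that("rate classification applies the 10 spikes/s boundary with IN at the boundary", {
  expect_equal(classify_unit(5), "RS")
  expect_equal(classify_unit(15), "IN")
  expect_equal(classify_unit(10), "IN")
  expect_error(classify_unit(-1), "non-negative")
})

test_that("spike-phase coupling reproduces circular-statistics identities", {
  fs <- 1000
  lfp <- sine(5, 100, fs)   # 5 Hz: phase 0 at t = k/5
  # all spikes at the same phase: |R| = 1
  at_peak <- (5:400) / 5
  c1 <- spike_phase_coupling(at_peak, lfp, fs, band = c(3, 8))
  expect_equal(c1$R, 1, tolerance = 1e-3)
  expect_equal(c1$preferred_phase, 0, tolerance = 0.05)
  # spikes alternating between phases 0 and pi/2: |R| = sqrt(2)/2 (oracle:
  # |mean(exp(i*0), exp(i*pi/2))| = sqrt(2)/2)
  quarter <- 1 / 5 / 4
  mixed <- sort(c(at_peak, at_peak + quarter))
  c2 <- spike_phase_coupling(mixed, lfp, fs, band = c(3, 8))
  expect_equal(c2$R, sqrt(2) / 2, tolerance = 0.01)
  expect_equal(c2$preferred_phase, pi / 4, tolerance = 0.05)
  expect_error(spike_phase_coupling(at_peak[1:5], lfp, fs), "insufficient")
})

test_that("coupling strength is invariant to LFP scaling and equivariant to phase rotation", {
  cfg <- single_osc_config(7, duration = 60, seed = 9)
  cfg$units <- list(unit_spec("IN", mean_rate = 60, coupling_strength = 0.5,
                              preferred_phase = 0.5))
  s <- generate_session(cfg)
  c1 <- spike_phase_coupling(s$spikes$unit1$times, s$lfp[1, ], s$fs)
  c2 <- spike_phase_coupling(s$spikes$unit1$times, 10 * s$lfp[1, ], s$fs)
  expect_equal(c1$R, c2$R, tolerance = 1e-10)
  expect_equal(c1$preferred_phase, c2$preferred_phase, tolerance = 1e-10)
  # shifting spikes by a quarter period rotates the preferred phase,
  # leaving |R| unchanged
  shift <- 1 / 7 / 4
  c3 <- spike_phase_coupling(s$spikes$unit1$times + shift, s$lfp[1, ], s$fs)
  expect_equal(c3$R, c1$R, tolerance = 0.05)
  dphi <- ((c3$preferred_phase - c1$preferred_phase + pi) %% (2 * pi)) - pi
  expect_equal(abs(dphi), pi / 2, tolerance = 0.15)
})

test_that("generator units are recovered with the right class through the summary pipeline", {
  cfg <- single_osc_config(7, duration = 60, seed = 13)
  cfg$units <- list(unit_spec("RS", mean_rate = 4, coupling_strength = 0.4),
                    unit_spec("IN", mean_rate = 30, coupling_strength = 0.3))
  s <- generate_session(cfg)
  for (j in 1:2) {
    u <- s$spikes[[j]]
    summ <- summarize_unit(paste0("u", j), u$times, u$template,
                           cfg$duration, lfp = s$lfp[1, ], fs = s$fs)
    expect_equal(summ$unit_class, u$spec$unit_class)
    expect_equal(summ$half_width, u$spec$half_width, tolerance = 0.05)
  }
})
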