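test_that("a noiseless single-oscillator session is a pure sinusoid at the configured frequency", {
  s <- generate_session(single_osc_config(8))
  psd <- compute_psd(s$lfp[1, ], s$fs)
  expect_equal(psd$freqs[which.max(psd$power)], 8, tolerance = 1e-6)
  # amplitude of the sinusoid survives generation
  expect_equal(max(abs(s$lfp[1, ])), 0.5, tolerance = 0.01)
})

test_that("identical configs generate bit-identical sessions", {
  cfg <- treadmill_config(duration = 40, stim_start = 20)
  cfg$units <- list(unit_spec("RS", mean_rate = 3))
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$lfp, s2$lfp)
  expect_identical(s1$tracking, s2$tracking)
  expect_identical(s1$spikes$unit1$times, s2$spikes$unit1$times)
})

test_that("stim-gated theta2 appears only during the stimulation epoch", {
  cfg <- treadmill_config(duration = 120, stim_start = 60, noise = 0.3)
  s <- generate_session(cfg)
  fs <- s$fs
  pre <- compute_psd(s$lfp[1, 1:(60 * fs)], fs)
  stim <- compute_psd(s$lfp[1, (60 * fs + 1):(120 * fs)], fs)
  pk_pre <- detect_theta_peaks(pre)
  pk_stim <- detect_theta_peaks(stim)
  expect_equal(nrow(pk_pre), 1)
  expect_equal(pk_pre$freq, 7.9, tolerance = 0.2 / 7.9)
  expect_equal(nrow(pk_stim), 2)
  expect_equal(pk_stim$freq[1], 6.8, tolerance = 0.2 / 6.8)
  expect_equal(pk_stim$freq[2], 7.9, tolerance = 0.2 / 7.9)
})

test_that("configured spike-phase coupling is recovered by the generator's own phase trace", {
  cfg <- single_osc_config(7, duration = 100, seed = 3)
  cfg$units <- list(unit_spec("IN", mean_rate = 100, coupling_strength = 0.6,
                              preferred_phase = 1))
  s <- generate_session(cfg)
  times <- s$spikes$unit1$times
  n <- length(times)
  expect_gt(n, 1000)
  # oracle: direct complex average of spike phases from the phase trace
  phik <- stats::approx(s$t, s$phases[[1]], times)$y
  mrv <- mean(exp(1i * phik))
  expect_lt(abs(Mod(mrv) - 0.6), 3 / sqrt(n))
  expect_lt(abs(Arg(mrv) - 1), 0.1)
})

test_that("uncoupled units produce uniform spike phases", {
  cfg <- single_osc_config(7, duration = 100, seed = 5)
  cfg$units <- list(unit_spec("IN", mean_rate = 100, coupling_strength = 0))
  s <- generate_session(cfg)
  times <- s$spikes$unit1$times
  phik <- stats::approx(s$t, s$phases[[1]], times)$y
  expect_lt(Mod(mean(exp(1i * phik))), 3 / sqrt(length(times)))
})

test_that("treadmill trajectories move at exactly the requested speed", {
  arena <- arena_spec()
  tr <- generate_trajectory(arena, 60, "treadmill", seed = 1,
                            params = list(speed = 10))
  sp <- tracking_speed(tr)
  expect_equal(mean(sp$speed), 10, tolerance = 0.01)
  expect_lt(max(abs(sp$speed - 10)), 0.2)
  r <- sqrt(tr$x^2 + tr$y^2)
  expect_true(all(r <= arena$radius + 1e-9))
})

test_that("random-walk trajectories are seed-deterministic and respect the wall bias", {
  arena <- arena_spec()
  t1 <- generate_trajectory(arena, 600, "random_walk_in_arena", seed = 1,
                            params = list(wall_bias = 0.8))
  t2 <- generate_trajectory(arena, 600, "random_walk_in_arena", seed = 1,
                            params = list(wall_bias = 0.8))
  expect_identical(t1, t2)
  occ <- mean(assign_zone(t1$x, t1$y, arena) == "Wall")
  expect_gte(occ, 0.7)
  expect_error(generate_trajectory(arena, 10, "flying"), "unknown")
})

test_that("invalid session configurations are rejected", {
  expect_error(oscillator_spec(-1), "base_freq")
  expect_error(oscillator_spec(7, gate = "zone_set"), "zones")
  expect_error(session_config(duration = 0), "duration")
  expect_error(session_config(fs = 500), "fs")
  expect_error(
    session_config(oscillators = list(oscillator_spec(7)),
                   pac = list(pac_spec(phase_source = 2))),
    "phase_source")
  expect_error(pac_spec(modulation_depth = 1.5), "modulation_depth")
})

test_that("PAC fidelity: modulation depth zero gives no coupling, MI increases with depth", {
  mis <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(d) {
    cfg <- session_config(duration = 60, n_channels = 1, channel_strata = "SP",
                          oscillators = list(oscillator_spec(7, amplitude = 0.5)),
                          pac = list(pac_spec(1, 70, 20, d, amplitude = 0.2)),
                          noise_amplitude = 0, seed = 2)
    s <- generate_session(cfg)
    mean_theta_gamma_mi(s$lfp[1, ], s$fs, gamma_band = c(60, 80))
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
  # depth 0: MI below the shuffled-surrogate 95th percentile
  cfg0 <- session_config(duration = 60, n_channels = 1, channel_strata = "SP",
                         oscillators = list(oscillator_spec(7, amplitude = 0.5)),
                         pac = list(pac_spec(1, 70, 20, 0, amplitude = 0.2)),
                         noise_amplitude = 0.3, seed = 2)
  s0 <- generate_session(cfg0)
  ph <- instantaneous_phase(bandpass(s0$lfp[1, ], s0$fs, 3, 10))
  am <- instantaneous_amplitude(bandpass(s0$lfp[1, ], s0$fs, 60, 80,
                                         order = 150))
  set.seed(1)
  st <- mi_surrogate_test(ph, am, s0$fs, n_surrogates = 100)
  expect_lt(st$mi, st$quantiles[[1]])
})
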