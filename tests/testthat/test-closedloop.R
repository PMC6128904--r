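test_that("baseline power equals chunk power for a stationary chunk-periodic tone", {
  fs <- 1000
  cc <- controller_config()
  # 8 Hz: exactly one cycle per 0.125 s chunk, so every chunk is identical
  sig <- sine(8, 40, fs, amplitude = 0.2)
  bp <- compute_baseline(sig, fs, cc)
  one <- thetawave:::chunk_band_power(sig[1:125], fs, cc$band, cc$pad_to)
  expect_equal(bp, one, tolerance = 1e-9)
  expect_error(compute_baseline(numeric(30 * fs), fs, cc), "zero")
  expect_error(compute_baseline(sig[1:1000], fs, cc), "shorter")
  # white-noise baseline: chunk power ratios distribute around 1
  set.seed(7)
  noise <- stats::rnorm(160 * fs)
  bpn <- compute_baseline(noise[1:(30 * fs)], fs, cc)
  ratios <- vapply(seq(30 * fs + 1, 160 * fs - 124, by = 125), function(s0) {
    thetawave:::chunk_band_power(noise[s0:(s0 + 124)], fs, cc$band,
                                 cc$pad_to) / bpn
  }, numeric(1))
  # baseline is the mean chunk power, so the ratio distribution has mean 1
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("the trigger boundary sits exactly at the power threshold and speed criterion", {
  fs <- 1000
  cc <- controller_config()
  base <- sine(8, 40, fs, amplitude = 0.2)
  bp <- compute_baseline(base, fs, cc)
  chunk8 <- sine(8, 0.125, fs, amplitude = 0.2)
  # power ratio switching point: bisection on the amplitude-scale factor
  fires <- function(k) cl_step(sqrt(k) * chunk8, 10, bp, fs, cc)$laser_on
  lo <- 1; hi <- 4
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, 2.5, tolerance = 0.01)
  # gate truth table at the printed constants
  expect_true(cl_step(sqrt(3) * chunk8, 10, bp, fs, cc)$laser_on)
  expect_false(cl_step(sqrt(2) * chunk8, 10, bp, fs, cc)$laser_on)
  expect_false(cl_step(sqrt(3) * chunk8, 3, bp, fs, cc)$laser_on)
  cc_imm <- controller_config(mode = "immobility")
  expect_true(cl_step(sqrt(3) * chunk8, 3, bp, fs, cc_imm)$laser_on)
  expect_false(cl_step(sqrt(3) * chunk8, 10, bp, fs, cc_imm)$laser_on)
  # the two modes are complementary away from exactly 5 cm/s, and both
  # reject exactly 5 cm/s (strict comparisons)
  for (v in c(4.9, 5.1)) {
    mv <- cl_step(sqrt(3) * chunk8, v, bp, fs, cc)$laser_on
    im <- cl_step(sqrt(3) * chunk8, v, bp, fs, cc_imm)$laser_on
    expect_true(xor(mv, im))
  }
  expect_false(cl_step(sqrt(3) * chunk8, 5, bp, fs, cc)$laser_on)
  expect_false(cl_step(sqrt(3) * chunk8, 5, bp, fs, cc_imm)$laser_on)
  expect_error(cl_step(chunk8[1:100], 10, bp, fs, cc), "chunk length")
})

test_that("replay triggers exactly during a theta2 burst and is deterministic", {
  cfg <- session_config(
    duration = 60, n_channels = 1, channel_strata = "SP",
    oscillators = list(
      oscillator_spec(8, amplitude = 0.1, name = "weak_base"),
      oscillator_spec(7, amplitude = 0.6, gate = "stim_on", name = "burst")),
    noise_amplitude = 0.02,
    trajectory_model = "treadmill", trajectory_params = list(speed = 10),
    stim_epochs = data.frame(start = 40, end = 45, freq = 16), seed = 5)
  s <- generate_session(cfg)
  log <- replay(s, controller_config())
  v <- validate_triggers(log, data.frame(start = 40, end = 45))
  expect_gte(v$sensitivity, 0.9)
  expect_gte(v$specificity, 0.98)
  expect_lte(v$median_latency_chunks, 1)
  # triggers confined to the burst plus at most one adjacent chunk
  on_t <- log$t_start[log$laser_on]
  expect_true(all(on_t >= 40 - 0.125 & on_t <= 45 + 0.125))
  # determinism
  expect_identical(replay(s, controller_config()), log)
  # speed gate suppresses everything in immobility mode (treadmill at 10)
  log_imm <- replay(s, controller_config(mode = "immobility"))
  expect_equal(sum(log_imm$laser_on), 0)
  expect_error(replay(list(lfp = s$lfp[, 1:1000, drop = FALSE], fs = s$fs,
                           tracking = s$tracking)), "baseline")
})

test_that("no triggers occur without theta2 and sensitivity collapses at infinite threshold", {
  cfg <- session_config(
    duration = 45, n_channels = 1, channel_strata = "SP",
    oscillators = list(oscillator_spec(8, amplitude = 0.1)),
    noise_amplitude = 0.02,
    trajectory_model = "treadmill", trajectory_params = list(speed = 10),
    seed = 6)
  s <- generate_session(cfg)
  log <- replay(s, controller_config())
  expect_equal(sum(log$laser_on), 0)
  # infinite threshold: sensitivity 0 even on a burst session
  cfg$oscillators <- c(cfg$oscillators,
                       list(oscillator_spec(7, amplitude = 0.6, gate = "stim_on")))
  cfg$stim_epochs <- data.frame(start = 35, end = 40, freq = 16)
  s2 <- generate_session(cfg)
  log2 <- replay(s2, controller_config(threshold = Inf))
  v2 <- validate_triggers(log2, data.frame(start = 35, end = 40))
  expect_equal(v2$sensitivity, 0)
  expect_error(validate_triggers(log2[0, ], data.frame(start = 1, end = 2)),
               "empty")
})

test_that("sensitivity jumps across the 2.5x amplitude-ratio boundary", {
  fs <- 1000
  cc <- controller_config()
  base <- sine(8, 40, fs, amplitude = 0.2)
  bp <- compute_baseline(base, fs, cc)
  sens <- vapply(c(1.5, 2.0, 2.6, 3, 4), function(k) {
    chunk <- sine(8, 0.125, fs, amplitude = 0.2 * sqrt(k))
    mean(vapply(1:20, function(i) cl_step(chunk, 10, bp, fs, cc)$laser_on,
                logical(1)))
  }, numeric(1))
  expect_equal(sens, c(0, 0, 1, 1, 1))
})
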