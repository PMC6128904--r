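test_that("zone assignment follows the inner-inclusive annulus convention", {
  arena <- arena_spec()
  expect_equal(assign_zone(0, 0, arena), "Center")
  expect_equal(assign_zone(25, 0, arena), "Wall")
  expect_equal(assign_zone(8, 0, arena), "Center")          # boundary: inner
  expect_equal(assign_zone(16, 0, arena), "Intermediate")
  expect_equal(assign_zone(30, 0, arena), "Wall")           # clipped
  expect_equal(assign_zone(c(0, 12, 18, 22), c(0, 0, 0, 0), arena),
               c("Center", "Intermediate", "ExtendedIntermediate", "Wall"))
  expect_error(arena_spec(zone_boundaries = c(8, 8, 20, 25)), "increasing")
})

test_that("zone metrics count crossings and partition session time", {
  arena <- arena_spec()
  fs_tr <- 50
  # constructed path: 100 s bouts alternating Wall and Intermediate,
  # so Wall -> Intermediate is crossed 3 times in 10 min
  t <- seq(0, 600 - 1 / fs_tr, by = 1 / fs_tr)
  r <- ifelse(floor(t / 100) %% 2 == 0, 22, 12)
  tr <- data.frame(t = t, x = r, y = 0)
  zm <- zone_metrics(tr, arena)
  expect_equal(sum(zm$time_in_zone), 600, tolerance = 0.01)
  expect_equal(as.numeric(zm$crossing_counts["Wall->Intermediate"]), 3)
  expect_equal(as.numeric(zm$crossing_counts["Intermediate->Wall"]), 2)
  expect_equal(as.numeric(zm$crossing_freq_per_min["Wall->Intermediate"]),
               0.3, tolerance = 1e-6)
  # crossing parity: |#(A->B) - #(B->A)| <= 1
  expect_lte(abs(zm$crossing_counts["Wall->Intermediate"] -
                 zm$crossing_counts["Intermediate->Wall"]), 1)
  # static trajectory: one zone, zero crossings
  zm0 <- zone_metrics(data.frame(t = t, x = 22, y = 0), arena)
  expect_equal(unname(zm0$time_in_zone["Wall"]), 600, tolerance = 0.01)
  expect_equal(nrow(zm0$crossings), 0)
  expect_error(zone_metrics(tr[0, ], arena), "empty")
})

test_that("boundary jitter is debounced to the hand-annotated crossing count", {
  arena <- arena_spec()
  fs_tr <- 50
  t <- seq(0, 60 - 1 / fs_tr, by = 1 / fs_tr)
  set.seed(8)
  # path hugging the Wall/ExtendedIntermediate boundary (20 cm) with jitter,
  # plus one genuine excursion to 12 cm at t in [30, 40): 2 true crossings
  r <- 20.2 + stats::rnorm(length(t), 0, 0.25)
  r[t >= 30 & t < 40] <- 12
  zm <- zone_metrics(data.frame(t = t, x = r, y = 0), arena)
  inter_cross <- sum(zm$crossings$to == "Intermediate" |
                     zm$crossings$from == "Intermediate")
  expect_equal(inter_cross, 2)
  # without debouncing the jitter would produce many more label changes
  raw_labels <- assign_zone(r, numeric(length(t)), arena)
  expect_gt(sum(raw_labels[-1] != raw_labels[-length(t)]), 10)
})

test_that("zone-segmented LFP windows split by occupancy and respect the walking filter", {
  arena <- arena_spec()
  fs <- 1000; fs_tr <- 50; dur <- 120
  tt <- seq(0, dur - 1 / fs_tr, by = 1 / fs_tr)
  # first half circling in Wall, second half in Center, walking speed 8 cm/s
  r <- ifelse(tt < dur / 2, 22, 4)
  omega <- 8 / r
  phi <- cumsum(omega) / fs_tr
  tr <- data.frame(t = tt, x = r * cos(phi), y = r * sin(phi))
  lfp <- sine(8, dur, fs)
  segs <- segment_lfp_by_zone(lfp, fs, tr, arena)
  counts <- table(segs$zone)
  expect_equal(unname(abs(counts["Wall"] - counts["Center"])) <= 2, TRUE)
  # all windows are walking windows at 8 cm/s
  segs_w <- segment_lfp_by_zone(lfp, fs, tr, arena, walking_filter = TRUE)
  expect_gt(nrow(segs_w), 0.8 * nrow(segs))
  # immobile session: the walking filter removes everything
  tr0 <- data.frame(t = tt, x = 22, y = 0)
  segs0 <- segment_lfp_by_zone(lfp, fs, tr0, arena, walking_filter = TRUE)
  expect_equal(nrow(segs0), 0)
  expect_error(segment_lfp_by_zone(lfp[1:(10 * fs)], fs, tr, arena),
               "misaligned")
})

test_that("per-zone PSDs reproduce zone-gated generator content", {
  cfg <- arena_config(duration = 240, seed = 11)
  s <- generate_session(cfg)
  segs <- segment_lfp_by_zone(s$lfp[1, ], s$fs, s$tracking, cfg$arena)
  zp <- zone_psd(s$lfp[1, ], segs)
  pk_wall <- detect_theta_peaks(zp$Wall)
  pk_int <- detect_theta_peaks(zp$Intermediate)
  # Wall: single theta1 peak at the slow-speed frequency
  expect_equal(nrow(pk_wall), 1)
  expect_equal(pk_wall$freq, 7.3, tolerance = 0.2 / 7.3)
  # Intermediate: theta2 and fast theta1
  expect_equal(nrow(pk_int), 2)
  expect_equal(pk_int$freq[1], 8.0, tolerance = 0.2 / 8)
  expect_equal(pk_int$freq[2], 9.5, tolerance = 0.2 / 9.5)
})
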