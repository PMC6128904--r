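# Shared fixtures, built in code at test time.

# single-channel session with one ungated oscillator
single_osc_config <- function(freq = 8, duration = 30, amplitude = 0.5,
                              noise = 0, seed = 1, ...) {
  session_config(duration = duration, n_channels = 1, channel_strata = "SP",
                 oscillators = list(oscillator_spec(freq, amplitude = amplitude)),
                 noise_amplitude = noise, seed = seed, ...)
}

# treadmill session with theta1 always on and theta2 gated by stimulation,
# configured at the 10 cm/s study frequencies
treadmill_config <- function(duration = 120, stim_start = 60,
                             noise = 0.3, seed = 1) {
  session_config(
    duration = duration, n_channels = 1, channel_strata = "SP",
    oscillators = list(
      oscillator_spec(7.9, amplitude = 0.5, name = "theta1"),
      oscillator_spec(6.8, amplitude = 0.5, gate = "stim_on", name = "theta2")),
    noise_amplitude = noise,
    trajectory_model = "treadmill", trajectory_params = list(speed = 10),
    stim_epochs = data.frame(start = stim_start, end = duration, freq = 16),
    seed = seed)
}

# arena session: speed-dependent theta1 (7.3 Hz at 7 cm/s in the Wall zone,
# 9.5 Hz at 25 cm/s in the Intermediate zone) plus zone-gated theta2
arena_config <- function(duration = 300, seed = 11, noise = 0.3) {
  slope <- (9.5 - 7.3) / (25 - 7)
  theta1 <- oscillator_spec(7.3 - slope * 7, amplitude = 0.5,
                            speed_slope = slope, name = "theta1")
  theta2 <- oscillator_spec(6.0, amplitude = 0.5, speed_slope = 0.08,
                            gate = "zone_set",
                            zones = c("Intermediate", "Center"),
                            name = "theta2")
  session_config(
    duration = duration, n_channels = 1, channel_strata = "SP",
    oscillators = list(theta1, theta2), noise_amplitude = noise,
    trajectory_model = "random_walk_in_arena",
    trajectory_params = list(zone_speeds = c(Wall = 7, Intermediate = 25),
                             wall_bias = 0.5, mean_dwell = 20),
    seed = seed)
}

sine <- function(freq, duration, fs = 1000, amplitude = 1, phase = 0) {
  amplitude * cos(2 * pi * freq * seq(0, duration - 1 / fs, by = 1 / fs) + phase)
}
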