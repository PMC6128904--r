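#' Oscillator specification for the session generator
#'
#' Describes one rhythmic LFP component. Its instantaneous frequency is
#' `base_freq + speed_slope * speed(t)` (phase is obtained by integrating the
#' instantaneous frequency, so speed changes never produce phase slips), and
#' its expression can be gated by stimulation, arena zone, or immobility.
#'
#' @param base_freq oscillation frequency (Hz) at zero speed.
#' @param amplitude peak amplitude (mV).
#' @param speed_slope frequency increase per unit running speed (Hz per cm/s).
#' @param gate one of `"always"`, `"stim_on"`, `"zone_set"`, `"immobility"`.
#' @param zones character vector of arena zone labels; required when
#'   `gate = "zone_set"`.
#' @param laminar_profile optional list with numeric vectors `gain` and
#'   `phase` (radians), one entry per channel; defaults to gain 1 / phase 0
#'   everywhere, with a phase reversal applied by [session_config()] defaults.
#' @param name optional identifier.
#' @return an object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(base_freq, amplitude = 0.5, speed_slope = 0,
                            gate = c("always", "stim_on", "zone_set", "immobility"),
                            zones = NULL, laminar_profile = NULL, name = NULL) {
  gate <- match.arg(gate)
  if (!is.numeric(base_freq) || base_freq <= 0) stop("base_freq must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (gate == "zone_set" && is.null(zones)) {
    stop("gate 'zone_set' requires a 'zones' vector")
  }
  structure(list(base_freq = base_freq, amplitude = amplitude,
                 speed_slope = speed_slope, gate = gate, zones = zones,
                 laminar_profile = laminar_profile, name = name),
            class = "oscillator_spec")
}

#' Phase-amplitude coupling specification
#'
#' A fast (gamma-band) component whose amplitude envelope is modulated by the
#' phase of a slower oscillator:
#' `env(t) = amplitude * (1 + depth * cos(phi(t) - preferred_phase)) / 2`.
#'
#' @param phase_source index of the oscillator (in the session config) whose
#'   phase drives the envelope.
#' @param amp_center_freq carrier frequency of the fast component (Hz).
#' @param amp_bandwidth carrier jitter bandwidth (Hz); 0 gives a pure carrier.
#' @param modulation_depth coupling depth in \[0, 1\]; 0 removes the coupling.
#' @param amplitude envelope maximum (mV).
#' @param preferred_phase slow-oscillation phase (radians) at which the fast
#'   amplitude peaks.
#' @return an object of class `pac_spec`.
#' @export
pac_spec <- function(phase_source = 1L, amp_center_freq = 70,
                     amp_bandwidth = 20, modulation_depth = 0.8,
                     amplitude = 0.2, preferred_phase = 0) {
  if (modulation_depth < 0 || modulation_depth > 1) {
    stop("modulation_depth must lie in [0, 1]")
  }
  if (amp_center_freq <= 0) stop("amp_center_freq must be > 0")
  structure(list(phase_source = as.integer(phase_source),
                 amp_center_freq = amp_center_freq,
                 amp_bandwidth = amp_bandwidth,
                 modulation_depth = modulation_depth,
                 amplitude = amplitude, preferred_phase = preferred_phase),
            class = "pac_spec")
}

#' Spiking-unit specification
#'
#' A point-process unit with a stereotyped biphasic waveform, a mean firing
#' rate, and von Mises phase locking to a theta oscillator. The concentration
#' parameter is chosen so the expected mean resultant vector length equals
#' `coupling_strength` exactly.
#'
#' @param unit_class `"RS"` (regular spiking) or `"IN"` (interneuron).
#' @param mean_rate mean firing rate (spikes/s).
#' @param coupling_strength target phase-locking strength |R| in \[0, 1\].
#' @param preferred_phase preferred theta phase (radians).
#' @param half_width waveform half-width (ms) of the principal deflection.
#' @param peak_trough_ratio amplitude ratio of the principal peak to the
#'   adjacent trough (large for RS, near 1 for IN).
#' @param phase_source index of the driving oscillator in the session config.
#' @return an object of class `unit_spec`.
#' @export
unit_spec <- function(unit_class = c("RS", "IN"), mean_rate = 5,
                      coupling_strength = 0.3, preferred_phase = 0,
                      half_width = if (match.arg(unit_class) == "RS") 0.36 else 0.23,
                      peak_trough_ratio = if (match.arg(unit_class) == "RS") 12.3 else 1.4,
                      phase_source = 1L) {
  unit_class <- match.arg(unit_class)
  if (mean_rate <= 0) stop("mean_rate must be > 0")
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("coupling_strength must lie in [0, 1]")
  }
  structure(list(unit_class = unit_class, mean_rate = mean_rate,
                 coupling_strength = coupling_strength,
                 preferred_phase = preferred_phase, half_width = half_width,
                 peak_trough_ratio = peak_trough_ratio,
                 phase_source = as.integer(phase_source)),
            class = "unit_spec")
}

#' Circular-arena geometry with concentric zones
#'
#' The arena is divided into concentric annuli: Center, Intermediate,
#' ExtendedIntermediate and Wall. A point on a zone boundary belongs to the
#' inner zone of the pair. The arena dimensions are a configurable default
#' (25 cm radius), since any consistent geometry supports the zone logic.
#'
#' @param radius arena radius (cm).
#' @param center arena center `(x, y)` (cm).
#' @param zone_boundaries strictly increasing outer radii of the zones; the
#'   last must equal `radius`.
#' @param zone_labels labels for the annuli, inner to outer.
#' @return an object of class `arena_spec`.
#' @export
arena_spec <- function(radius = 25, center = c(0, 0),
                       zone_boundaries = c(8, 16, 20, 25),
                       zone_labels = c("Center", "Intermediate",
                                       "ExtendedIntermediate", "Wall")) {
  if (any(diff(zone_boundaries) <= 0)) {
    stop("zone_boundaries must be strictly increasing")
  }
  if (length(zone_boundaries) != length(zone_labels)) {
    stop("one boundary per zone label required")
  }
  if (abs(zone_boundaries[length(zone_boundaries)] - radius) > 1e-9) {
    stop("last zone boundary must equal the arena radius")
  }
  structure(list(radius = radius, center = center,
                 zone_boundaries = zone_boundaries, zone_labels = zone_labels),
            class = "arena_spec")
}

default_strata <- function(n_channels) {
  # laminar ordering from stratum oriens down to lacunosum-moleculare
  cuts <- round(n_channels * c(0.125, 0.25, 0.625))
  labs <- character(n_channels)
  labs[seq_len(n_channels) <= cuts[1]] <- "SO"
  labs[seq_len(n_channels) > cuts[1] & seq_len(n_channels) <= cuts[2]] <- "SP"
  labs[seq_len(n_channels) > cuts[2] & seq_len(n_channels) <= cuts[3]] <- "SR"
  labs[labs == ""] <- "SLM"
  labs
}

#' Default laminar profile with an SP/SLM theta phase reversal
#'
#' Unit gain on all channels; theta phase offset of pi on SLM channels,
#' mimicking the polarity reversal between the pyramidal layer and the
#' lacunosum-moleculare seen on linear probes.
#'
#' @param strata character vector of per-channel stratum labels.
#' @return list with `gain` and `phase` vectors.
#' @export
default_laminar_profile <- function(strata) {
  list(gain = rep(1, length(strata)),
       phase = ifelse(strata == "SLM", pi, 0))
}

#' Session configuration for the synthetic generator
#'
#' Bundles every parameter that determines a synthetic recording session:
#' sampling, probe geometry, oscillators, phase-amplitude coupling, units,
#' background noise, arena and trajectory model, and stimulation epochs.
#' The seed fully determines the generated session.
#'
#' @param fs LFP sampling rate (Hz), at least 1000.
#' @param duration session length (s).
#' @param n_channels number of laminar probe channels.
#' @param channel_spacing inter-channel spacing (µm).
#' @param channel_strata per-channel stratum labels.
#' @param oscillators list of [oscillator_spec()] objects.
#' @param pac list of [pac_spec()] objects.
#' @param units list of [unit_spec()] objects.
#' @param noise_exponent 1/f^alpha exponent of the background noise.
#' @param noise_amplitude RMS amplitude of the background noise (mV).
#' @param arena an [arena_spec()].
#' @param trajectory_model `"treadmill"` or `"random_walk_in_arena"`.
#' @param trajectory_params list passed to [generate_trajectory()].
#' @param stim_epochs data frame with columns `start`, `end` (s) and `freq`
#'   (stimulation frequency, Hz); may have zero rows.
#' @param tracking_fs tracking sampling rate (Hz).
#' @param wideband_fs sampling rate for spike-waveform-carrying traces (Hz).
#' @param seed integer seed; identical configs generate identical sessions.
#' @return an object of class `session_config`.
#' @export
session_config <- function(fs = 1000, duration = 60, n_channels = 16,
                           channel_spacing = 100,
                           channel_strata = default_strata(n_channels),
                           oscillators = list(), pac = list(), units = list(),
                           noise_exponent = 1, noise_amplitude = 0.3,
                           arena = arena_spec(),
                           trajectory_model = c("treadmill", "random_walk_in_arena"),
                           trajectory_params = list(),
                           stim_epochs = data.frame(start = numeric(),
                                                    end = numeric(),
                                                    freq = numeric()),
                           tracking_fs = 50, wideband_fs = 25000,
                           seed = 1L) {
  trajectory_model <- match.arg(trajectory_model)
  if (fs < 1000) stop("fs must be at least 1000 Hz")
  if (duration <= 0) stop("duration must be positive")
  if (length(channel_strata) != n_channels) {
    stop("channel_strata must have one label per channel")
  }
  for (o in oscillators) {
    if (!inherits(o, "oscillator_spec")) stop("oscillators must be oscillator_spec objects")
    if (!is.null(o$laminar_profile) &&
        length(o$laminar_profile$gain) != n_channels) {
      stop("laminar_profile length must equal the channel count")
    }
    if (o$gate == "zone_set" && !all(o$zones %in% arena$zone_labels)) {
      stop("oscillator gate references unknown arena zone(s)")
    }
  }
  for (p in pac) {
    if (!inherits(p, "pac_spec")) stop("pac must be pac_spec objects")
    if (p$phase_source < 1L || p$phase_source > length(oscillators)) {
      stop("pac phase_source refers to a missing oscillator")
    }
    if (p$amp_center_freq <= oscillators[[p$phase_source]]$base_freq) {
      stop("pac amplitude frequency must exceed the phase oscillator frequency")
    }
  }
  for (u in units) {
    if (!inherits(u, "unit_spec")) stop("units must be unit_spec objects")
    if (u$phase_source < 1L || u$phase_source > max(1L, length(oscillators))) {
      stop("unit phase_source refers to a missing oscillator")
    }
  }
  if (nrow(stim_epochs) > 0 &&
      (any(stim_epochs$end <= stim_epochs$start) ||
       any(stim_epochs$start < 0) || any(stim_epochs$end > duration))) {
    stop("stim epochs must lie within the session with end > start")
  }
  structure(list(fs = fs, duration = duration, n_channels = n_channels,
                 channel_spacing = channel_spacing,
                 channel_strata = channel_strata, oscillators = oscillators,
                 pac = pac, units = units, noise_exponent = noise_exponent,
                 noise_amplitude = noise_amplitude, arena = arena,
                 trajectory_model = trajectory_model,
                 trajectory_params = trajectory_params,
                 stim_epochs = stim_epochs, tracking_fs = tracking_fs,
                 wideband_fs = wideband_fs, seed = as.integer(seed)),
            class = "session_config")
}
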