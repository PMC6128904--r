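#' Generate an animal trajectory in a circular arena
#'
#' Two movement models are provided. `"treadmill"` moves the animal along a
#' circular path at exactly the requested speed (constant-speed running, as
#' on a treadmill with a preset belt speed). `"random_walk_in_arena"`
#' alternates bouts between arena zones: each bout picks a zone (the Wall
#' zone with probability `wall_bias`, otherwise uniformly among the others
#' named in `zone_speeds`), moves radially to that zone's mid-annulus at the
#' zone's speed, then circles within it for an exponentially distributed
#' dwell time.
#'
#' @param arena an [arena_spec()].
#' @param duration trajectory length (s).
#' @param model `"treadmill"` or `"random_walk_in_arena"`.
#' @param seed integer seed; the seed fully determines the path.
#' @param params list of model parameters. Treadmill: `speed` (cm/s, default
#'   10). Random walk: `wall_bias` (probability of a Wall bout, default 0.6),
#'   `zone_speeds` (named vector of per-zone speeds in cm/s; its names define
#'   the visited zones), `mean_dwell` (mean bout duration, s, default 15).
#' @param fs tracking sampling rate (Hz).
#' @return data frame with columns `t`, `x`, `y` (class `tracking`).
#' @export
generate_trajectory <- function(arena, duration, model = c("treadmill", "random_walk_in_arena"),
                                seed = 1L, params = list(), fs = 50) {
  if (!inherits(arena, "arena_spec")) stop("arena must be an arena_spec")
  if (any(arena$zone_boundaries <= 0)) stop("arena radii must be positive")
  model <- tryCatch(match.arg(model),
                    error = function(e) stop("unknown trajectory model"))
  set.seed(as.integer(seed))
  t <- seq(0, duration, by = 1 / fs)
  t <- t[t < duration]
  n <- length(t)
  if (model == "treadmill") {
    speed <- if (is.null(params$speed)) 10 else params$speed
    r <- arena$radius / 2
    omega <- speed / r             # rad/s for constant tangential speed
    theta0 <- stats::runif(1, 0, 2 * pi)
    x <- arena$center[1] + r * cos(theta0 + omega * t)
    y <- arena$center[2] + r * sin(theta0 + omega * t)
  } else {
    zone_speeds <- params$zone_speeds
    if (is.null(zone_speeds)) {
      zone_speeds <- c(Wall = 7, Intermediate = 25)
    }
    if (!all(names(zone_speeds) %in% arena$zone_labels)) {
      stop("zone_speeds names must be arena zone labels")
    }
    wall_bias <- if (is.null(params$wall_bias)) 0.6 else params$wall_bias
    mean_dwell <- if (is.null(params$mean_dwell)) 15 else params$mean_dwell
    bounds <- c(0, arena$zone_boundaries)
    mid_radius <- function(zone) {
      i <- match(zone, arena$zone_labels)
      (bounds[i] + bounds[i + 1L]) / 2
    }
    zones <- names(zone_speeds)
    has_wall <- "Wall" %in% zones
    dt <- 1 / fs
    r <- numeric(n); phi <- numeric(n)
    cur_zone <- if (has_wall) "Wall" else zones[1L]
    r[1L] <- mid_radius(cur_zone)
    phi[1L] <- stats::runif(1, 0, 2 * pi)
    direction <- sample(c(-1, 1), 1)
    dwell_left <- max(2, stats::rexp(1, 1 / mean_dwell))
    for (i in 2:n) {
      v <- zone_speeds[[cur_zone]]
      target_r <- mid_radius(cur_zone)
      if (abs(r[i - 1L] - target_r) > v * dt) {
        # radial approach at the zone speed
        r[i] <- r[i - 1L] + sign(target_r - r[i - 1L]) * v * dt
        phi[i] <- phi[i - 1L]
      } else {
        r[i] <- target_r
        phi[i] <- phi[i - 1L] + direction * v * dt / max(r[i], 1e-6)
      }
      dwell_left <- dwell_left - dt
      if (dwell_left <= 0) {
        pick_wall <- has_wall && stats::runif(1) < wall_bias
        others <- setdiff(zones, "Wall")
        cur_zone <- if (pick_wall || length(others) == 0) "Wall"
                    else others[sample.int(length(others), 1)]
        dwell_left <- min(60, max(2, stats::rexp(1, 1 / mean_dwell)))
        if (stats::runif(1) < 0.2) direction <- -direction
      }
    }
    x <- arena$center[1] + r * cos(phi)
    y <- arena$center[2] + r * sin(phi)
  }
  out <- data.frame(t = t, x = x, y = y)
  class(out) <- c("tracking", "data.frame")
  out
}

#' Parametric biphasic spike waveform template
#'
#' Sum of two Gaussians: a trough followed by a peak, with exactly
#' controllable half-width (full width at half amplitude of the principal,
#' i.e. larger, deflection) and peak/trough amplitude ratio. Regular-spiking
#' templates have a dominant peak (ratio >> 1), interneuron templates are
#' nearly symmetric.
#'
#' @param half_width full width at half maximum of the principal deflection (ms).
#' @param peak_trough_ratio `|peak| / |trough|` amplitude ratio.
#' @param fs waveform sampling rate (Hz).
#' @param duration template length (ms).
#' @param amplitude amplitude of the principal deflection (µV).
#' @return numeric vector (class `waveform`) with attributes `fs` and
#'   `trough_index`.
#' @export
make_spike_template <- function(half_width = 0.36, peak_trough_ratio = 12.3,
                                fs = 25000, duration = 3.2, amplitude = 100) {
  t <- seq(0, duration, by = 1000 / fs)   # ms grid
  mid <- duration / 2
  # FWHM of a Gaussian = 2*sqrt(2*log(2))*sigma
  sigma_main <- half_width / (2 * sqrt(2 * log(2)))
  sigma_minor <- sigma_main
  sep <- 4 * sigma_main + 0.15            # keep the lobes from overlapping
  sep <- round(sep * fs / 1000) * 1000 / fs  # grid-align both lobe centers
  if (peak_trough_ratio >= 1) {
    # dominant positive peak preceded by a smaller trough
    trough_amp <- amplitude / peak_trough_ratio
    w <- -trough_amp * exp(-(t - (mid - sep))^2 / (2 * sigma_minor^2)) +
      amplitude * exp(-(t - mid)^2 / (2 * sigma_main^2))
  } else {
    peak_amp <- amplitude * peak_trough_ratio
    w <- -amplitude * exp(-(t - mid)^2 / (2 * sigma_main^2)) +
      peak_amp * exp(-(t - (mid + sep))^2 / (2 * sigma_minor^2))
  }
  structure(w, fs = fs, trough_index = which.min(w), class = "waveform")
}

# gate signal (0/1) for one oscillator, on the LFP time base
oscillator_gate <- function(osc, t, stim_on, zone, speed) {
  switch(osc$gate,
         always = rep(1, length(t)),
         stim_on = as.numeric(stim_on),
         zone_set = as.numeric(zone %in% osc$zones),
         immobility = as.numeric(speed < 5),
         stop("invalid gate reference: ", osc$gate))
}

#' Generate a complete synthetic recording session
#'
#' Builds a multi-channel laminar LFP as the sum of 1/f background noise,
#' gated oscillators whose instantaneous frequency follows running speed
#' through phase integration, and phase-amplitude-coupled gamma components;
#' plus tracking, stimulation epochs, and phase-locked spike trains drawn
#' from an inhomogeneous point process with von Mises phase modulation.
#' Identical configurations (same seed) produce bit-identical sessions.
#'
#' @param config a [session_config()].
#' @return an object of class `session_data`: list with elements `lfp`
#'   (channels x samples matrix, mV), `fs`, `t`, `tracking`, `speed` (cm/s on
#'   the LFP time base), `zone` (per-sample zone label), `stim_epochs`,
#'   `spikes` (per-unit list with `times`, `template`, `spec`), `phases`
#'   (per-oscillator instantaneous phase, radians), `config`.
#' @export
generate_session <- function(config) {
  if (!inherits(config, "session_config")) stop("config must be a session_config")
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  nch <- config$n_channels

  tracking <- generate_trajectory(config$arena, config$duration,
                                  config$trajectory_model,
                                  seed = config$seed + 1L,
                                  params = config$trajectory_params,
                                  fs = config$tracking_fs)
  sp <- tracking_speed(tracking)
  speed <- resample_series(sp$t, sp$speed, t)
  zone_track <- assign_zone(tracking$x, tracking$y, config$arena)
  zone <- zone_track[pmin(length(zone_track),
                          pmax(1L, floor(t * config$tracking_fs) + 1L))]

  stim_on <- rep(FALSE, n)
  if (nrow(config$stim_epochs) > 0) {
    for (k in seq_len(nrow(config$stim_epochs))) {
      stim_on <- stim_on | (t >= config$stim_epochs$start[k] &
                            t < config$stim_epochs$end[k])
    }
  }

  lfp <- matrix(0, nrow = nch, ncol = n)
  phases <- vector("list", length(config$oscillators))
  for (j in seq_along(config$oscillators)) {
    osc <- config$oscillators[[j]]
    f_inst <- osc$base_freq + osc$speed_slope * speed
    phi0 <- stats::runif(1, 0, 2 * pi)
    phi <- phi0 + 2 * pi * cumsum(f_inst) / fs
    phases[[j]] <- phi
    g <- oscillator_gate(osc, t, stim_on, zone, speed)
    prof <- osc$laminar_profile
    if (is.null(prof)) prof <- default_laminar_profile(config$channel_strata)
    s <- osc$amplitude * g
    for (ch in seq_len(nch)) {
      lfp[ch, ] <- lfp[ch, ] + prof$gain[ch] * s * cos(phi + prof$phase[ch])
    }
  }

  for (p in config$pac) {
    phi <- phases[[p$phase_source]]
    env <- p$amplitude * (1 + p$modulation_depth *
                            cos(phi - p$preferred_phase)) / 2
    if (p$amp_bandwidth > 0) {
      # band-limited Gaussian carrier: gamma is a noise process occupying
      # the band, not a coherent sinusoid with discrete AM sidebands
      carrier <- fir_bandpass(stats::rnorm(n), fs,
                              p$amp_center_freq - p$amp_bandwidth / 2,
                              p$amp_center_freq + p$amp_bandwidth / 2,
                              order = round(3 * fs / 10))
      carrier <- carrier / (stats::sd(carrier) * sqrt(2))
    } else {
      carrier <- cos(2 * pi * p$amp_center_freq * t +
                       stats::runif(1, 0, 2 * pi))
    }
    gsig <- env * carrier
    for (ch in seq_len(nch)) lfp[ch, ] <- lfp[ch, ] + gsig
  }

  if (config$noise_amplitude > 0) {
    for (ch in seq_len(nch)) {
      lfp[ch, ] <- lfp[ch, ] + pink_noise(n, fs, config$noise_exponent,
                                          config$noise_amplitude)
    }
  }

  spikes <- list()
  for (j in seq_along(config$units)) {
    u <- config$units[[j]]
    phi <- if (length(phases) >= u$phase_source) phases[[u$phase_source]] else NULL
    times <- draw_unit_spikes(u, phi, t, config$duration)
    template <- make_spike_template(u$half_width, u$peak_trough_ratio,
                                    fs = config$wideband_fs)
    spikes[[paste0("unit", j)]] <- list(times = times, template = template,
                                        spec = u)
  }

  structure(list(lfp = lfp, fs = fs, t = t, tracking = tracking,
                 speed = speed, zone = zone,
                 stim_epochs = config$stim_epochs, spikes = spikes,
                 phases = phases, config = config),
            class = "session_data")
}

# inhomogeneous Poisson spikes, rate modulated by a von Mises function of the
# driving oscillator phase; thinning against the rate maximum
draw_unit_spikes <- function(u, phi, t, duration) {
  kappa <- vonmises_kappa(u$coupling_strength)
  if (is.null(phi) || kappa == 0) {
    n_sp <- stats::rpois(1, u$mean_rate * duration)
    return(sort(stats::runif(n_sp, 0, duration)))
  }
  lmax <- u$mean_rate * exp(kappa) / besselI(kappa, 0)
  n_cand <- stats::rpois(1, lmax * duration)
  cand <- sort(stats::runif(n_cand, 0, duration))
  phi_c <- resample_series(t, phi, cand)
  rate <- u$mean_rate * exp(kappa * cos(phi_c - u$preferred_phase)) /
    besselI(kappa, 0)
  keep <- stats::runif(n_cand) < rate / lmax
  cand[keep]
}

#' @export
print.session_data <- function(x, ...) {
  cat("Synthetic recording session\n")
  cat(sprintf("  %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$lfp), ncol(x$lfp), x$fs, x$config$duration))
  cat(sprintf("  oscillators: %d, PAC components: %d, units: %d\n",
              length(x$config$oscillators), length(x$config$pac),
              length(x$spikes)))
  cat(sprintf("  stim epochs: %d, trajectory: %s\n",
              nrow(x$stim_epochs), x$config$trajectory_model))
  invisible(x)
}
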