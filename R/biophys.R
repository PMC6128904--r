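#' Simplified CA1 pyramidal-cell compartmental model
#'
#' A soma plus a 150 µm apical dendritic cable (10 segments by default)
#' with Hodgkin-Huxley-style conductances: Na and delayed-rectifier K in all
#' compartments, A-type K and M-current in the soma, and the
#' hyperpolarization-activated cation current Ih in the soma and along the
#' distal dendrite (0.01 µS total each, the dendritic total spread uniformly
#' over the cable). All kinetic parameters live in a single editable list so
#' channel variants can be swapped in.
#'
#' Units: mV, ms, µS, nA, nF, µm.
#'
#' @param n_dend number of dendritic segments.
#' @param dend_length total dendritic length (µm).
#' @param dend_diam dendritic diameter (µm).
#' @param soma_length,soma_diam soma cylinder dimensions (µm).
#' @param ra axial resistivity (Ohm cm).
#' @param cm specific capacitance (µF/cm^2).
#' @param g_pas passive conductance density (S/cm^2).
#' @param e_pas passive reversal (mV).
#' @param gna_soma,gna_dend,gkdr_soma,gkdr_dend,gka_soma,gkm_soma channel
#'   conductance densities (S/cm^2).
#' @param gh_soma_total,gh_dend_total Ih totals (µS) for the soma and the
#'   whole dendrite.
#' @param e_na,e_k,e_h reversal potentials (mV).
#' @param kinetics list of channel rate functions; defaults to
#'   [default_kinetics()].
#' @return object of class `cell_model`.
#' @export
cell_model <- function(n_dend = 10, dend_length = 150, dend_diam = 2,
                       soma_length = 20, soma_diam = 20, ra = 150, cm = 1,
                       g_pas = 1e-4, e_pas = -65,
                       gna_soma = 0.05, gna_dend = 0.005,
                       gkdr_soma = 0.012, gkdr_dend = 0.004,
                       gka_soma = 0.008, gkm_soma = 0.001,
                       gh_soma_total = 0.01, gh_dend_total = 0.01,
                       e_na = 50, e_k = -85, e_h = -30,
                       kinetics = default_kinetics()) {
  if (n_dend < 1) stop("at least soma + one dendritic segment required")
  ncomp <- n_dend + 1L
  seg_len <- dend_length / n_dend
  # compartment 1 = soma; 2..ncomp = dendrite, proximal to distal
  L <- c(soma_length, rep(seg_len, n_dend))
  diam <- c(soma_diam, rep(dend_diam, n_dend))
  area_cm2 <- pi * diam * L * 1e-8          # lateral area, µm^2 -> cm^2
  C <- cm * area_cm2 * 1e3                  # µF -> nF
  gbar <- function(dens_soma, dens_dend) {
    c(dens_soma * area_cm2[1], rep(dens_dend, n_dend) * area_cm2[-1]) * 1e6
  }
  g_na <- gbar(gna_soma, gna_dend)
  g_kdr <- gbar(gkdr_soma, gkdr_dend)
  g_ka <- gbar(gka_soma, 0)
  g_km <- gbar(gkm_soma, 0)
  g_l <- gbar(g_pas, g_pas)
  g_h <- c(gh_soma_total, rep(gh_dend_total / n_dend, n_dend))
  # axial conductances between adjacent compartment centers (µS)
  ax_cm2 <- pi * (diam * 1e-4)^2 / 4        # cross-section, cm^2
  half_r <- ra * (L * 1e-4 / 2) / ax_cm2 / 1e6   # MOhm per half-compartment
  g_ax <- 1 / (half_r[-ncomp] + half_r[-1])      # µS between i and i+1
  # compartment center coordinates (µm): soma at origin, dendrite along +y
  y <- c(0, soma_length / 2 + (seq_len(n_dend) - 0.5) * seg_len)
  coords <- cbind(x = rep(0, ncomp), y = y, z = rep(0, ncomp))
  structure(list(ncomp = ncomp, n_dend = n_dend, C = C, g_na = g_na,
                 g_kdr = g_kdr, g_ka = g_ka, g_km = g_km, g_l = g_l,
                 g_h = g_h, g_ax = g_ax, e_na = e_na, e_k = e_k, e_h = e_h,
                 e_pas = e_pas, coords = coords, area_cm2 = area_cm2,
                 kinetics = kinetics),
            class = "cell_model")
}

#' Default channel kinetics
#'
#' Canonical HH-style rate functions: transient Na (m^3 h), delayed
#' rectifier (n^4), A-type K (a b), muscarinic M-current, and the
#' hyperpolarization-activated Ih. Each entry returns steady state and time
#' constant (ms) at a membrane potential; edit or replace entries to change
#' channel behavior.
#'
#' @return named list of functions `V -> list(inf, tau)`.
#' @export
default_kinetics <- function() {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (exp(x / y) - 1))
  list(
    na_m = function(V) {
      a <- 0.1 * vtrap(-(V + 40), 10); b <- 4 * exp(-(V + 65) / 18)
      list(inf = a / (a + b), tau = pmax(1 / (a + b), 0.02))
    },
    na_h = function(V) {
      a <- 0.07 * exp(-(V + 65) / 20); b <- 1 / (1 + exp(-(V + 35) / 10))
      list(inf = a / (a + b), tau = pmax(1 / (a + b), 0.1))
    },
    kdr_n = function(V) {
      a <- 0.01 * vtrap(-(V + 55), 10); b <- 0.125 * exp(-(V + 65) / 80)
      list(inf = a / (a + b), tau = pmax(1 / (a + b), 0.3))
    },
    ka_a = function(V) list(inf = 1 / (1 + exp(-(V + 30) / 15)), tau = rep(1, length(V))),
    ka_b = function(V) list(inf = 1 / (1 + exp((V + 70) / 6)), tau = rep(15, length(V))),
    km_m = function(V) {
      list(inf = 1 / (1 + exp(-(V + 35) / 10)),
           tau = 1000 / (3.3 * (exp((V + 35) / 20) + exp(-(V + 35) / 20))) / 10)
    },
    h_r = function(V) {
      list(inf = 1 / (1 + exp((V + 80) / 8)),
           tau = 50 + 1000 / (exp((V + 70) / 20) + exp(-(V + 70) / 20)) / 10)
    }
  )
}

#' Synapse specification
#'
#' Alpha-function synaptic conductance `g(t) = g_max * (t/tau) * exp(1 - t/tau)`
#' per presynaptic event. Excitatory inputs (Schaffer / temporoammonic) use
#' tau 0.1 ms, 0.05 µS, 0 mV; inhibitory inputs (OLM onto the distal
#' dendrite, basket onto the soma) use tau 0.3 ms, 0.05 µS, -75 mV.
#'
#' @param kind `"excitatory"`, `"inhibitory_OLM"` or `"inhibitory_basket"`.
#' @param target target compartment index (1 = soma); defaults to the
#'   distal-most segment for excitatory/OLM, soma for basket.
#' @param tau alpha time constant (ms).
#' @param g_max peak conductance (µS).
#' @param e_rev reversal potential (mV).
#' @param events numeric vector of event times (ms).
#' @return object of class `synapse_spec`.
#' @export
synapse_spec <- function(kind = c("excitatory", "inhibitory_OLM",
                                  "inhibitory_basket"),
                         target = NULL, tau = NULL, g_max = 0.05,
                         e_rev = NULL, events = numeric()) {
  kind <- match.arg(kind)
  if (is.null(tau)) tau <- if (kind == "excitatory") 0.1 else 0.3
  if (is.null(e_rev)) e_rev <- if (kind == "excitatory") 0 else -75
  if (tau <= 0) stop("tau must be positive")
  if (g_max < 0) stop("g_max must be non-negative")
  structure(list(kind = kind, target = target, tau = tau, g_max = g_max,
                 e_rev = e_rev, events = events),
            class = "synapse_spec")
}

#' Rhythmic event train (e.g. OLM theta drive)
#'
#' Periodic volleys at a drive frequency; each volley is a short burst of
#' `burst_n` events at `burst_isi` spacing, with optional Gaussian jitter.
#'
#' @param freq drive frequency (Hz).
#' @param duration train length (s).
#' @param burst_n events per volley.
#' @param burst_isi intra-burst interval (ms).
#' @param jitter SD of Gaussian event jitter (ms).
#' @param t0 first volley time (ms).
#' @return event times (ms), sorted.
#' @export
rhythmic_train <- function(freq, duration, burst_n = 5, burst_isi = 2,
                           jitter = 0, t0 = 50) {
  period <- 1000 / freq
  starts <- seq(t0, duration * 1000 - period / 2, by = period)
  ev <- as.vector(outer(starts, (seq_len(burst_n) - 1) * burst_isi, `+`))
  if (jitter > 0) ev <- ev + stats::rnorm(length(ev), 0, jitter)
  sort(ev[ev >= 0 & ev <= duration * 1000])
}

# alpha-kernel conductance series for one synapse on a dt grid (µS)
alpha_conductance <- function(events, tau, g_max, n_steps, dt) {
  g <- numeric(n_steps)
  if (length(events) == 0 || g_max == 0) return(g)
  klen <- min(n_steps, ceiling(10 * tau / dt))
  tk <- (seq_len(klen) - 1) * dt
  kern <- g_max * (tk / tau) * exp(1 - tk / tau)
  for (ev in events) {
    i0 <- floor(ev / dt) + 1L
    if (i0 > n_steps) next
    i1 <- min(n_steps, i0 + klen - 1L)
    g[i0:i1] <- g[i0:i1] + kern[seq_len(i1 - i0 + 1L)]
  }
  g
}

#' Simulate the compartmental model
#'
#' Integrates the cable equation with an implicit (backward Euler) voltage
#' step and Rush-Larsen exponential updates of the gating variables.
#' Transmembrane currents are recovered from the axial current balance, so
#' their spatial sum is zero at every step (charge bookkeeping), making the
#' extracellular point-source sum dipolar at a distance.
#'
#' @param model a [cell_model()].
#' @param synapses list of [synapse_spec()] objects with event times.
#' @param duration simulated time (s).
#' @param dt time step (ms), at most 0.025.
#' @param v_init initial membrane potential (mV).
#' @param record_stride keep every `record_stride`-th sample in the output.
#' @return object of class `cell_sim`: list with `t` (ms), `vm`
#'   (compartments x time, mV), `im` (transmembrane currents, nA, outward
#'   positive), `model`, `dt`.
#' @export
simulate_cell <- function(model, synapses = list(), duration = 1,
                          dt = 0.025, v_init = -65, record_stride = 1L) {
  stopifnot(inherits(model, "cell_model"))
  if (dt > 0.025 + 1e-12) stop("dt must be at most 0.025 ms")
  nc <- model$ncomp
  n_steps <- round(duration * 1000 / dt)
  for (s in synapses) {
    if (length(s$events) && max(s$events) > duration * 1000) {
      stop("synaptic event times must lie within the simulated duration")
    }
  }
  # per-compartment synaptic conductance series; untargeted distal inputs
  # (OLM, temporoammonic/Schaffer excitation) are spread across the distal
  # third of the cable, as their axons arborize over the distal domain
  syn_g <- list(); syn_e <- numeric(0); syn_target <- integer(0)
  distal <- seq.int(nc - max(1L, ceiling(model$n_dend / 3)) + 1L, nc)
  for (s in synapses) {
    targets <- s$target
    if (is.null(targets)) {
      targets <- if (s$kind == "inhibitory_basket") 1L else distal
    }
    g_series <- alpha_conductance(s$events, s$tau, s$g_max / length(targets),
                                  n_steps, dt)
    for (tgt in targets) {
      syn_g[[length(syn_g) + 1L]] <- g_series
      syn_e <- c(syn_e, s$e_rev)
      syn_target <- c(syn_target, tgt)
    }
  }
  kin <- model$kinetics
  V <- rep(v_init, nc)
  m <- kin$na_m(V)$inf; h <- kin$na_h(V)$inf; n <- kin$kdr_n(V)$inf
  a <- kin$ka_a(V)$inf; b <- kin$ka_b(V)$inf
  km <- kin$km_m(V)$inf; r <- kin$h_r(V)$inf
  keep <- seq(1L, n_steps, by = record_stride)
  vm_out <- matrix(NA_real_, nc, length(keep))
  im_out <- matrix(NA_real_, nc, length(keep))
  kidx <- 1L
  gax <- model$g_ax
  C_dt <- model$C / dt
  up <- c(gax, 0); lo <- c(0, gax)      # axial couplings (i,i+1)
  for (step in seq_len(n_steps)) {
    gna <- model$g_na * m^3 * h
    gkdr <- model$g_kdr * n^4
    gka <- model$g_ka * a * b
    gkm <- model$g_km * km
    gh <- model$g_h * r
    g_tot <- gna + gkdr + gka + gkm + gh + model$g_l
    ge <- gna * model$e_na + (gkdr + gka + gkm) * model$e_k +
      gh * model$e_h + model$g_l * model$e_pas
    if (length(syn_g)) {
      for (si in seq_along(syn_g)) {
        gs <- syn_g[[si]][step]
        if (gs > 0) {
          tgt <- syn_target[si]
          g_tot[tgt] <- g_tot[tgt] + gs
          ge[tgt] <- ge[tgt] + gs * syn_e[si]
        }
      }
    }
    # backward Euler: (C/dt + g_tot + axial) V_new = C/dt V + ge (tridiagonal)
    dd <- C_dt + g_tot + up + lo
    rhs <- C_dt * V + ge
    V <- solve_tridiag(dd, -gax, -gax, rhs)
    # gating update (Rush-Larsen)
    s1 <- kin$na_m(V); m <- s1$inf + (m - s1$inf) * exp(-dt / s1$tau)
    s1 <- kin$na_h(V); h <- s1$inf + (h - s1$inf) * exp(-dt / s1$tau)
    s1 <- kin$kdr_n(V); n <- s1$inf + (n - s1$inf) * exp(-dt / s1$tau)
    s1 <- kin$ka_a(V); a <- s1$inf + (a - s1$inf) * exp(-dt / s1$tau)
    s1 <- kin$ka_b(V); b <- s1$inf + (b - s1$inf) * exp(-dt / s1$tau)
    s1 <- kin$km_m(V); km <- s1$inf + (km - s1$inf) * exp(-dt / s1$tau)
    s1 <- kin$h_r(V); r <- s1$inf + (r - s1$inf) * exp(-dt / s1$tau)
    if (any(abs(V) > 150)) {
      stop(sprintf("numerical divergence at t = %.3f ms (|Vm| > 150 mV)",
                   step * dt))
    }
    if (step == keep[kidx]) {
      vm_out[, kidx] <- V
      # membrane current (outward +) = net axial current into the compartment
      ax_in <- numeric(nc)
      dV <- diff(V)
      ax_in[-nc] <- ax_in[-nc] + gax * dV
      ax_in[-1] <- ax_in[-1] - gax * dV
      im_out[, kidx] <- ax_in
      kidx <- kidx + 1L
      if (kidx > length(keep)) kidx <- length(keep)
    }
  }
  structure(list(t = (keep - 1L) * dt, vm = vm_out, im = im_out,
                 model = model, dt = dt, record_stride = record_stride),
            class = "cell_sim")
}

# Thomas algorithm for a symmetric tridiagonal system
solve_tridiag <- function(d, lower, upper, rhs) {
  n <- length(d)
  if (n == 1L) return(rhs / d)
  cp <- numeric(n - 1L); dp <- numeric(n)
  cp[1L] <- upper[1L] / d[1L]
  dp[1L] <- rhs[1L] / d[1L]
  for (i in 2:n) {
    denom <- d[i] - lower[i - 1L] * cp[i - 1L]
    if (i < n) cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i - 1L] * dp[i - 1L]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

#' Extracellular potentials from simulated membrane currents
#'
#' Point-source forward model in a homogeneous ohmic medium:
#' `phi_e(t) = 1/(4 pi sigma) * sum_k I_k(t) / r_ek`, summing every
#' compartment's transmembrane current over its distance to the electrode.
#'
#' @param sim a `cell_sim` from [simulate_cell()].
#' @param electrodes matrix (n x 3) of electrode positions (µm) relative to
#'   the soma center, or a vector of length 3 for a single electrode.
#' @param sigma extracellular conductivity (S/m).
#' @return matrix (electrodes x time) of potentials (µV).
#' @export
extracellular_potential <- function(sim, electrodes, sigma = 0.3) {
  stopifnot(inherits(sim, "cell_sim"))
  if (is.null(dim(electrodes))) electrodes <- matrix(electrodes, nrow = 1)
  coords <- sim$model$coords
  out <- matrix(0, nrow(electrodes), ncol(sim$im))
  for (e in seq_len(nrow(electrodes))) {
    r_um <- sqrt(colSums((t(coords) - electrodes[e, ])^2))
    if (any(r_um < 1e-9)) stop("electrode coincides with a compartment center")
    # I [nA] / (4 pi sigma [S/m] r [m]) -> V; report µV
    w <- 1e-9 / (4 * pi * sigma * (r_um * 1e-6)) * 1e6
    out[e, ] <- as.numeric(w %*% sim$im)
  }
  out
}

#' Theta-band CSD of a simulated laminar recording
#'
#' Places a colinear electrode grid along the somato-dendritic axis,
#' computes extracellular potentials, feeds them to [compute_csd()] and
#' reports the band-limited CSD amplitude per electrode.
#'
#' @param sim a `cell_sim`.
#' @param depths electrode positions along the dendritic axis (µm; 0 at the
#'   soma, positive toward the distal dendrite).
#' @param lateral_offset perpendicular distance of the grid from the cell
#'   axis (µm).
#' @param sigma extracellular conductivity (S/m).
#' @param band analysis band (Hz).
#' @return list with `csd` (a `csd_map`), `amplitude` (per retained
#'   electrode band RMS), `depths_retained`, `phi` (electrode potentials).
#' @export
csd_of_simulation <- function(sim, depths = seq(-60, 210, by = 30),
                              lateral_offset = 30, sigma = 0.3,
                              band = c(4, 12)) {
  if (length(depths) < 3) stop("at least 3 colinear electrodes required")
  electrodes <- cbind(lateral_offset, depths, 0)
  phi <- extracellular_potential(sim, electrodes, sigma)
  spacing <- diff(depths)[1]
  csd <- compute_csd(phi, spacing)
  fs_sim <- 1000 / (sim$dt * sim$record_stride)
  amp <- band_csd_amplitude(csd, band, fs_sim)
  list(csd = csd, amplitude = amp,
       depths_retained = depths[csd$channels], phi = phi)
}

#' Rhythmic rebound amplitude under OLM-type inhibition
#'
#' Drives the model with a rhythmic inhibitory train on the distal dendrite
#' (after a settling period without input) and measures the rhythmic rebound
#' depolarization of the soma: the theta-band (4-12 Hz) oscillation
#' amplitude of the somatic membrane potential in the driven steady state.
#' This is the membrane correlate of the theta power the inhibition
#' induces, and it isolates the rebound from slow baseline drift.
#'
#' @param model a [cell_model()].
#' @param freq drive frequency (Hz).
#' @param duration total simulated time (s), including `settle`.
#' @param settle input-free settling period (s).
#' @param burst_n,burst_isi volley structure (see [rhythmic_train()]).
#' @param dt integration step (ms).
#' @return list with `rebound` (mV, theta-band RMS of somatic Vm),
#'   `peak_times` (ms, somatic depolarization peaks per drive cycle),
#'   `sim`, `v_rest`.
#' @export
rebound_amplitude <- function(model, freq = 7, duration = 1.2, settle = 0.3,
                              burst_n = 5, burst_isi = 2, dt = 0.025) {
  period <- 1000 / freq
  train <- rhythmic_train(freq, duration, burst_n, burst_isi,
                          t0 = settle * 1000)
  olm <- synapse_spec("inhibitory_OLM", events = train)
  # record at ~2 kHz: ample for theta-band membrane dynamics
  stride <- max(1L, round(0.5 / dt))
  sim <- simulate_cell(model, list(olm), duration, dt,
                       record_stride = stride)
  v <- sim$vm[1, ]
  t <- sim$t
  v_rest <- v[max(which(t < settle * 1000))]
  drive <- t > settle * 1000 + 2 * period & t < duration * 1000 - period / 2
  fs_sim <- 1000 / (dt * sim$record_stride)
  vb <- fir_bandpass(v[drive] - mean(v[drive]), fs_sim, 4, 12)
  volleys <- seq(settle * 1000 + 2 * period, duration * 1000 - period,
                 by = period)
  peak_times <- vapply(volleys, function(t0) {
    sel <- t > t0 + burst_n * burst_isi & t <= t0 + period
    if (!any(sel)) return(NA_real_)
    t[sel][which.max(v[sel])]
  }, numeric(1))
  list(rebound = sqrt(mean(vb^2)), peak_times = peak_times, sim = sim,
       v_rest = v_rest)
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("Compartmental CA1 cell: soma + %d dendritic segments, distal tip at %.0f um\n",
              x$n_dend, max(x$coords[, "y"])))
  invisible(x)
}
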