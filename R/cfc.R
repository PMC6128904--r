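#' Zero-phase FIR bandpass filter
#'
#' Hamming-windowed linear-phase FIR applied forward and backward
#' (zero net phase shift). Filter order defaults to three cycles of the low
#' cutoff frequency, the convention of common EEG filtering routines.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz), `0 < lo < hi < fs/2`.
#' @param order optional FIR order override.
#' @return filtered numeric vector of the same length.
#' @export
bandpass <- function(signal, fs, lo, hi, order = NULL) {
  fir_bandpass(as.numeric(signal), fs, lo, hi, order)
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic representation, wrapped to (-pi, pi]. Phase 0
#' corresponds to the oscillation peak (cosine convention).
#'
#' @param filtered numeric vector, already band-limited.
#' @return numeric vector of phases (radians).
#' @export
instantaneous_phase <- function(filtered) {
  wrap_phase(Arg(analytic_signal(filtered)))
}

#' Amplitude envelope of a band-limited signal
#'
#' Modulus of the analytic representation.
#'
#' @param filtered numeric vector, already band-limited.
#' @return numeric vector of instantaneous amplitudes.
#' @export
instantaneous_amplitude <- function(filtered) {
  Mod(analytic_signal(filtered))
}

#' Entropy-based modulation index
#'
#' Mean fast-oscillation amplitude is computed in `n_bins` slow-oscillation
#' phase bins and normalized to a distribution P; the modulation index is
#' the normalized Kullback-Leibler divergence of P from uniform,
#' `MI = (log N - H(P)) / log N`, lying in \[0, 1\]: 0 for amplitude
#' independent of phase, 1 when all amplitude concentrates in a single bin.
#'
#' @param phase numeric vector of phases (radians).
#' @param amplitude numeric vector of amplitudes, same length.
#' @param n_bins number of phase bins (default 18, i.e. 20 degrees each).
#' @return scalar MI.
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude)) stop("phase/amplitude length mismatch")
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (all(amplitude == 0)) stop("amplitude is identically zero")
  bins <- phase_bin_index(phase, n_bins)
  mean_amp <- numeric(n_bins)
  sums <- rowsum(amplitude, bins)
  cnts <- tabulate(bins, n_bins)
  present <- as.integer(rownames(sums))
  mean_amp[present] <- sums[, 1] / pmax(cnts[present], 1L)
  P <- mean_amp / sum(mean_amp)
  H <- -sum(ifelse(P > 0, P * log(P), 0))
  (log(n_bins) - H) / log(n_bins)
}

phase_bin_index <- function(phase, n_bins) {
  idx <- floor((wrap_phase(phase) + pi) / (2 * pi) * n_bins) + 1L
  pmin(pmax(idx, 1L), n_bins)
}

#' Phase-amplitude comodulogram
#'
#' Modulation index for every pair of phase band (0.5 Hz windows at 0.25 Hz
#' steps) and amplitude band (10 Hz windows at 2.5 Hz steps), each band
#' extracted with the zero-phase FIR filter and the Hilbert transform.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param phase_range `c(lo, hi)` range of phase-frequency centers (Hz).
#' @param amp_range `c(lo, hi)` range of amplitude-frequency centers (Hz).
#' @param phase_window,phase_step phase filter width and center step (Hz).
#' @param amp_window,amp_step amplitude filter width and center step (Hz).
#' @param n_bins phase bins for the modulation index.
#' @return object of class `comodulogram`: list with `phase_freqs`,
#'   `amp_freqs`, `mi` (phase x amplitude matrix), `n_phase_bins`.
#' @export
comodulogram <- function(signal, fs, phase_range = c(4, 12),
                         amp_range = c(30, 100), phase_window = 0.5,
                         phase_step = 0.25, amp_window = 10, amp_step = 2.5,
                         n_bins = 18) {
  signal <- as.numeric(signal)
  phase_freqs <- seq(phase_range[1], phase_range[2], by = phase_step)
  amp_freqs <- seq(amp_range[1], amp_range[2], by = amp_step)
  if (max(amp_freqs) + amp_window / 2 >= fs / 2) {
    stop("amplitude range exceeds the Nyquist frequency")
  }
  # amplitude filters use a fixed 3-cycles-of-20-Hz order so that the slow
  # (phase) band falls deep in their stopband regardless of the band center
  amp_order <- round(3 * fs / 20)
  amp_env <- lapply(amp_freqs, function(fa) {
    instantaneous_amplitude(bandpass(signal, fs, fa - amp_window / 2,
                                     fa + amp_window / 2, order = amp_order))
  })
  mi <- matrix(NA_real_, length(phase_freqs), length(amp_freqs))
  for (i in seq_along(phase_freqs)) {
    fp <- phase_freqs[i]
    ph <- instantaneous_phase(bandpass(signal, fs,
                                       max(fp - phase_window / 2, 0.1),
                                       fp + phase_window / 2))
    bins <- phase_bin_index(ph, n_bins)
    cnts <- tabulate(bins, n_bins)
    for (j in seq_along(amp_freqs)) {
      sums <- rowsum(amp_env[[j]], bins)
      mean_amp <- numeric(n_bins)
      present <- as.integer(rownames(sums))
      mean_amp[present] <- sums[, 1] / pmax(cnts[present], 1L)
      P <- mean_amp / sum(mean_amp)
      H <- -sum(ifelse(P > 0, P * log(P), 0))
      mi[i, j] <- (log(n_bins) - H) / log(n_bins)
    }
  }
  structure(list(phase_freqs = phase_freqs, amp_freqs = amp_freqs, mi = mi,
                 n_phase_bins = n_bins),
            class = "comodulogram")
}

#' Location of the comodulogram maximum
#'
#' @param cmg a `comodulogram`.
#' @return list with `phase_freq`, `amp_freq`, `mi` at the global maximum.
#' @export
comodulogram_peak <- function(cmg) {
  stopifnot(inherits(cmg, "comodulogram"))
  ij <- arrayInd(which.max(cmg$mi), dim(cmg$mi))
  list(phase_freq = cmg$phase_freqs[ij[1]], amp_freq = cmg$amp_freqs[ij[2]],
       mi = cmg$mi[ij[1], ij[2]])
}

#' Mean theta-gamma modulation index
#'
#' Single MI using a 3-10 Hz phase band and a 30-80 Hz amplitude band, the
#' summary used to compare theta-gamma coupling across conditions.
#'
#' @param signal numeric vector, at least 10 s long.
#' @param fs sampling rate (Hz).
#' @param theta_band,gamma_band phase and amplitude bands (Hz).
#' @param n_bins phase bins.
#' @return scalar MI.
#' @export
mean_theta_gamma_mi <- function(signal, fs, theta_band = c(3, 10),
                                gamma_band = c(30, 80), n_bins = 18) {
  if (length(signal) < 10 * fs) stop("signal must be at least 10 s long")
  ph <- instantaneous_phase(bandpass(signal, fs, theta_band[1], theta_band[2]))
  am <- instantaneous_amplitude(bandpass(signal, fs, gamma_band[1],
                                         gamma_band[2],
                                         order = round(3 * fs / 20)))
  modulation_index(ph, am, n_bins)
}

#' Surrogate significance threshold for the modulation index
#'
#' Phase-shuffling surrogate distribution: the amplitude series is circularly
#' shifted by random offsets of at least `min_shift` seconds, breaking the
#' phase-amplitude relationship while preserving both marginals, and the MI
#' recomputed for each surrogate.
#'
#' @param phase,amplitude series as in [modulation_index()].
#' @param fs sampling rate (Hz).
#' @param n_surrogates number of surrogates.
#' @param min_shift minimum circular shift (s).
#' @param n_bins phase bins.
#' @param probs quantiles of the surrogate distribution to report.
#' @return list with `mi` (observed), `surrogates`, `quantiles`.
#' @export
mi_surrogate_test <- function(phase, amplitude, fs, n_surrogates = 200,
                              min_shift = 1, n_bins = 18, probs = 0.95) {
  n <- length(amplitude)
  lo <- round(min_shift * fs)
  if (n <= 2 * lo) stop("series too short for the requested minimum shift")
  shifts <- sample(seq(lo, n - lo), n_surrogates, replace = TRUE)
  sur <- vapply(shifts, function(s) {
    modulation_index(phase, c(amplitude[(s + 1):n], amplitude[1:s]), n_bins)
  }, numeric(1))
  list(mi = modulation_index(phase, amplitude, n_bins), surrogates = sur,
       quantiles = stats::quantile(sur, probs))
}

#' @export
print.comodulogram <- function(x, ...) {
  pk <- comodulogram_peak(x)
  cat(sprintf("Comodulogram: %d phase x %d amplitude bands; max MI %.4g at (%.2f, %.1f) Hz\n",
              length(x$phase_freqs), length(x$amp_freqs), pk$mi,
              pk$phase_freq, pk$amp_freq))
  invisible(x)
}

#' @export
plot.comodulogram <- function(x, ...) {
  graphics::image(x$phase_freqs, x$amp_freqs, x$mi,
                  xlab = "Phase frequency (Hz)",
                  ylab = "Amplitude frequency (Hz)", ...)
  invisible(x)
}
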