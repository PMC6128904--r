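#' Threshold spike detection on a wideband trace
#'
#' The trace is bandpass filtered 500-5000 Hz; spikes are negative threshold
#' crossings at `-threshold_sd` times the robust noise SD
#' (`median(|x|)/0.6745`), with a 1 ms refractory lockout; each waveform is
#' cut +/-0.8 ms around the trough.
#'
#' @param signal wideband numeric vector (µV).
#' @param fs sampling rate (Hz), at least 10 kHz.
#' @param threshold_sd detection threshold in noise-SD multiples.
#' @param band detection filter band (Hz).
#' @return list with `times` (s), `waveforms` (spikes x samples matrix) and
#'   `threshold` (µV).
#' @export
detect_spikes <- function(signal, fs, threshold_sd = 4, band = c(500, 5000)) {
  if (fs < 10000) stop("fs must be at least 10 kHz for spike detection")
  signal <- as.numeric(signal)
  if (length(signal) == 0) {
    return(list(times = numeric(), waveforms = matrix(0, 0, 0),
                threshold = NA_real_))
  }
  filt <- fir_bandpass(signal, fs, band[1], min(band[2], fs / 2 - 1))
  noise_sd <- stats::median(abs(filt)) / 0.6745
  thr <- -threshold_sd * noise_sd
  below <- filt < thr
  onsets <- which(below & !c(FALSE, below[-length(below)]))
  half <- round(0.0008 * fs)
  lockout <- round(0.001 * fs)
  times <- integer(0)
  last <- -Inf
  for (o in onsets) {
    if (o - last < lockout) next
    win <- o:min(o + lockout, length(filt))
    trough <- win[which.min(filt[win])]
    times <- c(times, trough)
    last <- trough
  }
  times <- times[times - half >= 1 & times + half <= length(filt)]
  wf <- if (length(times)) {
    t(vapply(times, function(i) filt[(i - half):(i + half)],
             numeric(2L * half + 1L)))
  } else matrix(0, 0, 2L * half + 1L)
  list(times = (times - 1L) / fs, waveforms = wf, threshold = thr)
}

#' Spike waveform features
#'
#' Half-width is the full width of the principal (largest-amplitude)
#' deflection at half of its extremal amplitude, with linear interpolation at
#' the half-amplitude crossings. The peak/trough ratio is `|peak| / |trough|`
#' of the principal positive peak and its adjacent trough, oriented so that
#' regular-spiking cells (dominant peak) give ratios well above 1 and
#' interneurons ratios near 1.
#'
#' @param w numeric waveform (µV) or a `waveform` from
#'   [make_spike_template()].
#' @param fs waveform sampling rate (Hz); taken from the waveform attribute
#'   when present.
#' @return list with `half_width` (ms) and `peak_trough_ratio`.
#' @export
waveform_features <- function(w, fs = attr(w, "fs")) {
  if (is.null(fs)) stop("fs must be supplied")
  x <- as.numeric(w)
  i_peak <- which.max(x)
  i_trough <- which.min(x)
  if (x[i_peak] <= 0 || x[i_trough] >= 0) {
    stop("waveform must contain both a trough and a peak")
  }
  ratio <- abs(x[i_peak]) / abs(x[i_trough])
  # principal deflection: the lobe with the larger absolute amplitude
  if (abs(x[i_peak]) >= abs(x[i_trough])) {
    lobe <- x; i0 <- i_peak
  } else {
    lobe <- -x; i0 <- i_trough
  }
  halfamp <- lobe[i0] / 2
  left <- i0
  while (left > 1L && lobe[left - 1L] > halfamp) left <- left - 1L
  right <- i0
  while (right < length(lobe) && lobe[right + 1L] > halfamp) right <- right + 1L
  if (left == 1L || right == length(lobe)) {
    stop("principal deflection not fully contained in the waveform")
  }
  # linear interpolation of the two half-amplitude crossings
  fl <- (lobe[left] - halfamp) / (lobe[left] - lobe[left - 1L])
  fr <- (lobe[right] - halfamp) / (lobe[right] - lobe[right + 1L])
  width_samples <- (right + fr) - (left - fl)
  list(half_width = width_samples * 1000 / fs, peak_trough_ratio = ratio)
}

#' Classify a unit as regular spiking or interneuron by firing rate
#'
#' Regular-spiking (RS) cells fire below 10 spikes/s, interneurons (IN)
#' above. The boundary rate of exactly 10 spikes/s is assigned to IN (a
#' documented convention; the strict inequalities of the rule leave it
#' undefined).
#'
#' @param mean_rate mean firing rate (spikes/s).
#' @param boundary rate separating the classes (spikes/s).
#' @return `"RS"` or `"IN"`.
#' @export
classify_unit <- function(mean_rate, boundary = 10) {
  if (any(mean_rate < 0)) stop("mean_rate must be non-negative")
  ifelse(mean_rate < boundary, "RS", "IN")
}

#' Spike-field theta-phase coupling
#'
#' The LFP is bandpass filtered (3-8 Hz by default), each spike time is
#' assigned the instantaneous phase of the filtered signal, and the coupling
#' strength is the length of the mean resultant vector
#' `|R| = |mean(exp(i*phi_k))|`, with the preferred phase its argument.
#'
#' @param spike_times numeric vector of spike times (s); at least 10 spikes.
#' @param lfp numeric LFP vector.
#' @param fs LFP sampling rate (Hz).
#' @param band theta filter band (Hz).
#' @return list with `R`, `preferred_phase` (radians), `phases` (per spike),
#'   `n_spikes`.
#' @export
spike_phase_coupling <- function(spike_times, lfp, fs, band = c(3, 8)) {
  duration <- length(lfp) / fs
  spike_times <- spike_times[spike_times >= 0 & spike_times < duration]
  if (length(spike_times) < 10) {
    stop("insufficient sample: fewer than 10 spikes within the recording")
  }
  phi <- instantaneous_phase(bandpass(lfp, fs, band[1], band[2]))
  idx <- pmin(length(phi), pmax(1L, round(spike_times * fs) + 1L))
  phases <- phi[idx]
  mrv <- mean(exp(1i * phases))
  list(R = Mod(mrv), preferred_phase = Arg(mrv), phases = phases,
       n_spikes = length(phases))
}

#' Summarize a detected unit
#'
#' Convenience wrapper producing the per-unit summary used in reports:
#' rate-based class, waveform features, and theta-phase coupling.
#'
#' @param unit_id identifier.
#' @param spike_times spike times (s).
#' @param waveform mean waveform (µV).
#' @param duration recording duration (s).
#' @param lfp,fs optional LFP for phase coupling.
#' @param waveform_fs waveform sampling rate (Hz).
#' @return one-row data frame (class `unit_summary`).
#' @export
summarize_unit <- function(unit_id, spike_times, waveform, duration,
                           lfp = NULL, fs = NULL,
                           waveform_fs = attr(waveform, "fs")) {
  rate <- length(spike_times) / duration
  feats <- waveform_features(waveform, waveform_fs)
  coup <- if (!is.null(lfp) && length(spike_times) >= 10) {
    spike_phase_coupling(spike_times, lfp, fs)
  } else list(R = NA_real_, preferred_phase = NA_real_)
  out <- data.frame(unit_id = unit_id, mean_rate = rate,
                    unit_class = classify_unit(rate),
                    half_width = feats$half_width,
                    peak_trough_ratio = feats$peak_trough_ratio,
                    coupling_R = coup$R, preferred_phase = coup$preferred_phase)
  class(out) <- c("unit_summary", "data.frame")
  out
}

#' Optogenetic tagging test
#'
#' A unit is considered light-tagged when its spike probability within
#' `window` seconds of light onsets exceeds `factor` times the baseline
#' probability in windows of the same length.
#'
#' @param spike_times spike times (s).
#' @param light_onsets light onset times (s).
#' @param duration recording duration (s).
#' @param window latency window (s).
#' @param factor required ratio over baseline.
#' @return list with `tagged` (logical), `p_light`, `p_baseline`.
#' @export
opto_tagged <- function(spike_times, light_onsets, duration, window = 0.01,
                        factor = 3) {
  if (length(light_onsets) == 0) stop("no light onsets supplied")
  hits <- vapply(light_onsets, function(t0) {
    any(spike_times >= t0 & spike_times < t0 + window)
  }, logical(1))
  p_light <- mean(hits)
  p_base <- min(1, length(spike_times) * window / duration)
  list(tagged = p_light > factor * p_base, p_light = p_light,
       p_baseline = p_base)
}
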