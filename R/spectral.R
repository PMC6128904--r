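#' Welch power spectral density
#'
#' Averaged periodogram over Hamming-tapered, overlapping, constant-detrended
#' segments (3 s windows with 2.5 s overlap by default). The one-sided
#' density is scaled so that its integral approximates the signal variance
#' (Parseval consistency); frequency resolution is `1/window_length`.
#'
#' @param signal numeric vector (mV).
#' @param fs sampling rate (Hz).
#' @param window_length segment length (s).
#' @param overlap segment overlap (s); must be shorter than the window.
#' @return object of class `power_spectrum`: list with `freqs`, `power`,
#'   `normalization` (`"raw"`), `window_length`, `overlap`, `n_segments`.
#' @export
compute_psd <- function(signal, fs, window_length = 3, overlap = 2.5) {
  signal <- as.numeric(signal)
  L <- round(window_length * fs)
  if (length(signal) < L) stop("signal shorter than one window")
  if (overlap >= window_length) stop("overlap must be shorter than the window")
  step <- max(1L, round((window_length - overlap) * fs))
  starts <- seq(1L, length(signal) - L + 1L, by = step)
  w <- as.numeric(signal::hamming(L))
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- signal[s0:(s0 + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    P <- (Mod(X)^2) / (fs * U)
    # one-sided: double all bins except DC (and Nyquist when L is even)
    mult <- rep(2, nf); mult[1L] <- 1
    if (L %% 2L == 0L) mult[nf] <- 1
    acc <- acc + P * mult
  }
  structure(list(freqs = (seq_len(nf) - 1L) * fs / L,
                 power = acc / length(starts),
                 normalization = "raw",
                 window_length = window_length, overlap = overlap,
                 n_segments = length(starts)),
            class = "power_spectrum")
}

# build a power_spectrum from an externally averaged periodogram
as_power_spectrum <- function(freqs, power, window_length, overlap,
                              n_segments = 1L, normalization = "raw") {
  structure(list(freqs = freqs, power = power, normalization = normalization,
                 window_length = window_length, overlap = overlap,
                 n_segments = n_segments),
            class = "power_spectrum")
}

#' Normalize a PSD by baseline total 0-14 Hz power
#'
#' Divides every power value by the baseline spectrum's integrated power over
#' 0-14 Hz, the convention used to merge spectra across animals (a baseline
#' normalized by itself integrates to exactly 1 over 0-14 Hz).
#'
#' @param psd a `power_spectrum` to normalize.
#' @param baseline_psd the pre-stimulation baseline `power_spectrum`; must
#'   share the frequency grid of `psd`.
#' @param band integration band of the normalizer (Hz).
#' @return a `power_spectrum` with `normalization = "baseline_total_0_14"`.
#' @export
normalize_psd <- function(psd, baseline_psd, band = c(0, 14)) {
  stopifnot(inherits(psd, "power_spectrum"),
            inherits(baseline_psd, "power_spectrum"))
  if (length(psd$freqs) != length(baseline_psd$freqs) ||
      any(abs(psd$freqs - baseline_psd$freqs) > 1e-9)) {
    stop("frequency grids of the two spectra do not match")
  }
  sel <- baseline_psd$freqs >= band[1] & baseline_psd$freqs <= band[2]
  total <- trapz(baseline_psd$freqs[sel], baseline_psd$power[sel])
  if (total <= 0) stop("baseline power over the normalization band is zero")
  out <- psd
  out$power <- psd$power / total
  out$normalization <- "baseline_total_0_14"
  out
}

#' Band definition
#'
#' @param name band label.
#' @param lo,hi band edges (Hz), `0 < lo < hi`.
#' @return object of class `band_definition`.
#' @export
band_definition <- function(name, lo, hi) {
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' Integrated band power
#'
#' Trapezoidal integral of a power spectrum over a frequency band. Band
#' edges falling between grid points are included by linear interpolation,
#' so `band_power(lo, hi) == band_power(lo, m) + band_power(m, hi)`.
#'
#' @param psd a `power_spectrum`.
#' @param band a [band_definition()] or numeric `c(lo, hi)`.
#' @return scalar integrated power.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "power_spectrum"))
  if (inherits(band, "band_definition")) band <- c(band$lo, band$hi)
  lo <- band[1]; hi <- band[2]
  fr <- psd$freqs
  if (lo < fr[1] || hi > fr[length(fr)]) stop("band outside the frequency grid")
  grid <- sort(unique(c(lo, hi, fr[fr > lo & fr < hi])))
  pw <- stats::approx(fr, psd$power, xout = grid)$y
  trapz(grid, pw)
}

#' Detect theta peaks in a power spectrum
#'
#' Finds local maxima within a search band that exceed the local 1/f trend
#' (a log-log linear fit over `trend_band`, excluding the search band) by a
#' prominence factor. At most `max_peaks` are returned, the most prominent
#' first selected, then sorted by frequency. Peak frequencies are refined by
#' quadratic interpolation of log power around the maximum bin.
#'
#' @param psd a `power_spectrum` (raw or normalized).
#' @param search_lo,search_hi search band (Hz).
#' @param prominence_factor required ratio of peak power to the 1/f trend.
#' @param max_peaks maximum number of peaks returned.
#' @param trend_band band over which the 1/f trend is fitted (Hz).
#' @return data frame with columns `freq` and `power` (possibly empty).
#' @export
detect_theta_peaks <- function(psd, search_lo = 4, search_hi = 12,
                               prominence_factor = 1.5, max_peaks = 2,
                               trend_band = c(2, 20)) {
  stopifnot(inherits(psd, "power_spectrum"))
  fr <- psd$freqs; pw <- psd$power
  fit_sel <- fr >= trend_band[1] & fr <= trend_band[2] &
    !(fr >= search_lo & fr <= search_hi) & pw > 0
  if (sum(fit_sel) >= 3) {
    fit <- stats::lm(log(pw[fit_sel]) ~ log(fr[fit_sel]))
    trend <- exp(fit$coefficients[1] + fit$coefficients[2] * log(pmax(fr, 1e-6)))
  } else {
    trend <- rep(stats::median(pw[pw > 0]), length(fr))
  }
  idx <- which(fr >= search_lo & fr <= search_hi)
  idx <- idx[idx > 1L & idx < length(fr)]
  is_max <- pw[idx] > pw[idx - 1L] & pw[idx] >= pw[idx + 1L]
  cand <- idx[is_max & pw[idx] > prominence_factor * trend[idx]]
  if (length(cand) == 0) {
    return(data.frame(freq = numeric(), power = numeric()))
  }
  prominence <- pw[cand] / trend[cand]
  cand <- cand[order(prominence, decreasing = TRUE)][seq_len(min(max_peaks, length(cand)))]
  cand <- sort(cand)
  freq <- vapply(cand, function(i) {
    # quadratic (log-power) interpolation for sub-bin frequency accuracy
    y <- log(pw[(i - 1L):(i + 1L)])
    denom <- y[1] - 2 * y[2] + y[3]
    delta <- if (abs(denom) > 1e-12) 0.5 * (y[1] - y[3]) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    fr[i] + delta * (fr[2] - fr[1])
  }, numeric(1))
  data.frame(freq = freq, power = pw[cand])
}

#' Time-frequency spectrogram
#'
#' Sliding-window periodogram: each column is the single-segment
#' Hamming-tapered periodogram of the window starting at that time (the same
#' estimator as [compute_psd()] without averaging).
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_length window length (s).
#' @param step hop between consecutive windows (s).
#' @return object of class `spectrogram`: list with `t` (window start
#'   times), `freqs`, `power` (freqs x time matrix).
#' @export
spectrogram <- function(signal, fs, window_length = 3, step = 0.5) {
  signal <- as.numeric(signal)
  L <- round(window_length * fs)
  if (length(signal) < L) stop("signal shorter than one window")
  starts <- seq(1L, length(signal) - L + 1L, by = max(1L, round(step * fs)))
  w <- as.numeric(signal::hamming(L))
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  mult <- rep(2, nf); mult[1L] <- 1
  if (L %% 2L == 0L) mult[nf] <- 1
  P <- vapply(starts, function(s0) {
    seg <- signal[s0:(s0 + L - 1L)]
    seg <- (seg - mean(seg)) * w
    (Mod(stats::fft(seg)[seq_len(nf)])^2) / (fs * U) * mult
  }, numeric(nf))
  structure(list(t = (starts - 1L) / fs, freqs = (seq_len(nf) - 1L) * fs / L,
                 power = P, window_length = window_length, step = step),
            class = "spectrogram")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum: %d bins, %.3g-%.4g Hz, %s (%d segments)\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$normalization, x$n_segments))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, xlim = c(0, 20), ...) {
  sel <- x$freqs >= xlim[1] & x$freqs <= xlim[2]
  graphics::plot(x$freqs[sel], x$power[sel], type = "l",
                 xlab = "Frequency (Hz)",
                 ylab = if (x$normalization == "raw") "Power (mV^2/Hz)"
                        else "Normalized power", ...)
  invisible(x)
}
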