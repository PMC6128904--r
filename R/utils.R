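#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic representation `x + i*H(x)` of a real series,
#' from which instantaneous phase (`Arg`) and amplitude envelope (`Mod`) are
#' derived.
#'
#' @param x numeric vector, a real-valued (ideally band-limited) signal.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("signal too short for analytic representation")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Power-law (1/f^alpha) background noise
#'
#' Spectrally shaped white Gaussian noise, the standard model for the
#' broadband background of extracellular field potentials. The amplitude
#' spectrum of unit-variance white noise is scaled by `f^(-alpha/2)` and the
#' result rescaled to a target RMS amplitude.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param alpha spectral exponent of the power spectrum (power ~ 1/f^alpha).
#' @param amplitude target RMS amplitude (mV).
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, alpha = 1, amplitude = 1) {
  if (n < 2L) stop("n must be at least 2")
  if (amplitude == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freqs <- c(0, seq_len(n - 1L)) * fs / n
  # two-sided frequency axis: mirror the upper half
  half <- freqs > fs / 2
  freqs[half] <- fs - freqs[half]
  scale <- c(0, freqs[-1L]^(-alpha / 2))
  x <- Re(stats::fft(W * scale, inverse = TRUE) / n)
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (amplitude / s)
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

# wrap angles to (-pi, pi]
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# linear interpolation of a series sampled at `t_from` onto `t_to`
resample_series <- function(t_from, x, t_to) {
  stats::approx(t_from, x, xout = t_to, rule = 2)$y
}

# invert |R| = I1(kappa)/I0(kappa) for the von Mises concentration
vonmises_kappa <- function(R) {
  stopifnot(R >= 0, R < 1)
  if (R < 1e-8) return(0)
  f <- function(k) besselI(k, 1) / besselI(k, 0) - R
  stats::uniroot(f, c(1e-8, 700), tol = 1e-10)$root
}

# zero-phase FIR bandpass used throughout; order = 3 cycles of the low
# cutoff (the eegfilt convention), capped so filtfilt's edge padding fits.
fir_bandpass <- function(x, fs, lo, hi, order = NULL) {
  if (!(lo > 0 && hi > lo && hi < fs / 2)) {
    stop("invalid band: need 0 < lo < hi < fs/2")
  }
  n <- length(x)
  if (is.null(order)) order <- round(3 * fs / lo)
  order <- min(order, floor((n - 4L) / 3))
  if (order %% 2L == 1L) order <- order - 1L
  if (order < 6L) stop("signal too short to filter at this band")
  b <- signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

# majority vote of a label vector (ties broken by first occurrence)
majority_label <- function(labels) {
  tab <- table(labels)
  names(tab)[which.max(tab)]
}
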