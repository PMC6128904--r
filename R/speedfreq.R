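#' Time-binned running speeds
#'
#' Divides a session into contiguous time bins (200 ms by default) and
#' reports the mean running speed per bin, plus the majority arena zone when
#' an arena is supplied.
#'
#' @param tracking data frame with `t`, `x`, `y`.
#' @param bin_length bin length (s).
#' @param arena optional [arena_spec()] for zone labels.
#' @return data frame with `t_start`, `speed`, and `zone` (NA without an
#'   arena).
#' @export
bin_speeds <- function(tracking, bin_length = 0.2, arena = NULL) {
  if (is.null(tracking) || nrow(tracking) == 0) stop("tracking is empty")
  sp <- tracking_speed(tracking)
  labels <- if (!is.null(arena)) assign_zone(tracking$x, tracking$y, arena)
            else rep(NA_character_, nrow(tracking))
  dt <- stats::median(diff(tracking$t))
  duration <- max(tracking$t) + dt
  n_bins <- floor(duration / bin_length + 1e-9)
  bin <- pmin(n_bins, floor(sp$t / bin_length) + 1L)
  keep <- bin >= 1L & bin <= n_bins
  speed <- as.numeric(tapply(sp$speed[keep], factor(bin[keep], levels = seq_len(n_bins)), mean))
  zone <- vapply(seq_len(n_bins), function(b) {
    l <- labels[keep][bin[keep] == b]
    if (length(l) == 0 || all(is.na(l))) NA_character_ else majority_label(l)
  }, character(1))
  data.frame(t_start = (seq_len(n_bins) - 1L) * bin_length, speed = speed,
             zone = zone)
}

#' Speed-binned relative-power map
#'
#' The distribution of time-bin speeds is divided into `n_speed_bins` equal
#' speed bins; for every speed bin, the discrete-Fourier-transform power of
#' all member LFP time bins is averaged (each bin zero-padded for frequency
#' interpolation) and normalized to relative power (each speed-bin row sums
#' to 1 over the analysis band).
#'
#' @param lfp numeric vector (one channel).
#' @param fs sampling rate (Hz).
#' @param speed_bins data frame from [bin_speeds()]; optionally pre-filtered
#'   to one zone.
#' @param band analysis band (Hz).
#' @param n_speed_bins number of speed bins.
#' @param bin_length LFP time-bin length (s); must match `speed_bins`.
#' @param pad_to zero-padding length (s) for DFT interpolation.
#' @param zone optional zone label; keeps only time bins in that zone.
#' @return object of class `speed_frequency_map`: list with
#'   `speed_bin_centers`, `freqs`, `rel_power` (speed x freq matrix, rows of
#'   empty bins are NA), `counts`.
#' @export
speed_frequency_map <- function(lfp, fs, speed_bins, band = c(1, 20),
                                n_speed_bins = 30, bin_length = 0.2,
                                pad_to = 4, zone = NULL) {
  sb <- speed_bins
  if (!is.null(zone)) sb <- sb[!is.na(sb$zone) & sb$zone == zone, , drop = FALSE]
  sb <- sb[!is.na(sb$speed), , drop = FALSE]
  if (nrow(sb) == 0) stop("no usable time bins")
  L <- round(bin_length * fs)
  nfft <- 2^ceiling(log2(pad_to * fs))
  nf <- nfft / 2 + 1L
  freqs_all <- (seq_len(nf) - 1L) * fs / nfft
  fsel <- freqs_all >= band[1] & freqs_all <= band[2]
  freqs <- freqs_all[fsel]
  # per-time-bin zero-padded periodogram
  pw <- matrix(NA_real_, nrow(sb), sum(fsel))
  for (i in seq_len(nrow(sb))) {
    s0 <- round(sb$t_start[i] * fs) + 1L
    if (s0 + L - 1L > length(lfp)) next
    seg <- lfp[s0:(s0 + L - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(c(seg, numeric(nfft - L)))[seq_len(nf)]
    pw[i, ] <- (Mod(X)^2)[fsel]
  }
  ok <- stats::complete.cases(pw)
  sb <- sb[ok, , drop = FALSE]; pw <- pw[ok, , drop = FALSE]
  edges <- seq(min(sb$speed), max(sb$speed), length.out = n_speed_bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  bin_of <- pmin(n_speed_bins, pmax(1L, findInterval(sb$speed, edges,
                                                     rightmost.closed = TRUE)))
  rel <- matrix(NA_real_, n_speed_bins, sum(fsel))
  counts <- tabulate(bin_of, n_speed_bins)
  for (b in seq_len(n_speed_bins)) {
    if (counts[b] == 0) next
    avg <- colMeans(pw[bin_of == b, , drop = FALSE])
    rel[b, ] <- avg / sum(avg)
  }
  structure(list(speed_bin_centers = centers, freqs = freqs,
                 rel_power = rel, counts = counts, band = band),
            class = "speed_frequency_map")
}

#' Per-frequency power-speed correlation
#'
#' For every frequency, relative power is regressed on speed-bin center
#' (weighted by the number of time bins per speed bin); frequencies are
#' classified as positively/negatively correlated at `p < alpha`, or
#' unrelated.
#'
#' @param map a `speed_frequency_map`.
#' @param alpha significance level (default 0.001).
#' @return data frame with `freq`, `slope`, `r`, `p`, `class` in
#'   `{"positive", "negative", "none"}`.
#' @export
power_speed_correlation <- function(map, alpha = 0.001) {
  stopifnot(inherits(map, "speed_frequency_map"))
  ok <- map$counts > 0 & stats::complete.cases(map$rel_power)
  if (sum(ok) < 5) stop("fewer than 5 non-empty speed bins")
  v <- map$speed_bin_centers[ok]
  wt <- map$counts[ok]
  res <- lapply(seq_along(map$freqs), function(j) {
    y <- map$rel_power[ok, j]
    if (stats::sd(y) == 0) {
      return(data.frame(freq = map$freqs[j], slope = 0, r = 0, p = 1,
                        class = "none"))
    }
    fit <- stats::lm(y ~ v, weights = wt)
    sm <- suppressWarnings(summary(fit))  # noiseless inputs fit perfectly
    slope <- stats::coef(fit)[2]
    p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                   lower.tail = FALSE)
    r <- sign(slope) * sqrt(sm$r.squared)
    cls <- if (p < alpha && slope > 0) "positive"
           else if (p < alpha && slope < 0) "negative" else "none"
    data.frame(freq = map$freqs[j], slope = slope, r = r, p = p, class = cls)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Ridge frequency per speed bin
#'
#' Frequency of maximal relative power per non-empty speed bin, optionally
#' restricted to a sub-band; used to recover the frequency-speed slope.
#'
#' @param map a `speed_frequency_map`.
#' @param band optional restriction band (Hz).
#' @return data frame with `speed` and `ridge_freq` (NA for empty bins
#'   removed).
#' @export
ridge_frequencies <- function(map, band = NULL) {
  sel <- if (is.null(band)) rep(TRUE, length(map$freqs))
         else map$freqs >= band[1] & map$freqs <= band[2]
  rows <- which(map$counts > 0 & stats::complete.cases(map$rel_power))
  data.frame(speed = map$speed_bin_centers[rows],
             ridge_freq = vapply(rows, function(b) {
               map$freqs[sel][which.max(map$rel_power[b, sel])]
             }, numeric(1)))
}

#' @export
print.speed_frequency_map <- function(x, ...) {
  cat(sprintf("Speed-frequency map: %d speed bins (%d non-empty) x %d frequencies (%g-%g Hz)\n",
              length(x$speed_bin_centers), sum(x$counts > 0),
              length(x$freqs), x$band[1], x$band[2]))
  invisible(x)
}
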