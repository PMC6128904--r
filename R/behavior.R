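#' Assign arena zone labels to positions
#'
#' Zones are concentric annuli; a point is labeled by its radial distance
#' from the arena center, with boundaries assigned to the inner zone of the
#' pair. Points outside the arena are clipped to the outermost (Wall) zone.
#'
#' @param x,y coordinates (cm); vectors of equal length.
#' @param arena an [arena_spec()].
#' @return character vector of zone labels.
#' @export
assign_zone <- function(x, y, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  r <- sqrt((x - arena$center[1])^2 + (y - arena$center[2])^2)
  r <- pmin(r, arena$radius)
  # boundaries are inner-inclusive: zone i covers (b_{i-1}, b_i]
  idx <- vapply(r, function(ri) {
    which(ri <= arena$zone_boundaries + 1e-12)[1]
  }, integer(1))
  arena$zone_labels[idx]
}

#' Running speed from tracking
#'
#' Positions are smoothed with a 0.2 s moving average and speed is the
#' centered finite difference of the smoothed path.
#'
#' @param tracking data frame with columns `t`, `x`, `y`.
#' @param smooth_window smoothing window (s).
#' @return data frame with columns `t` and `speed` (cm/s).
#' @export
tracking_speed <- function(tracking, smooth_window = 0.2) {
  n <- nrow(tracking)
  if (n < 3) stop("tracking too short to estimate speed")
  dt <- stats::median(diff(tracking$t))
  k <- max(1L, round(smooth_window / dt))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- function(v) {
    if (k == 1L) return(v)
    as.numeric(stats::filter(v, rep(1 / k, k), sides = 2)) -> out
    out[is.na(out)] <- v[is.na(out)]
    out
  }
  xs <- sm(tracking$x); ys <- sm(tracking$y)
  vx <- c(xs[2] - xs[1], (xs[-(1:2)] - xs[-((n - 1):n)]) / 2,
          xs[n] - xs[n - 1]) / dt
  vy <- c(ys[2] - ys[1], (ys[-(1:2)] - ys[-((n - 1):n)]) / 2,
          ys[n] - ys[n - 1]) / dt
  data.frame(t = tracking$t, speed = sqrt(vx^2 + vy^2))
}

#' Zone timeline and crossing/time metrics
#'
#' Assigns a zone to every tracking sample, suppresses boundary jitter with
#' a 0.2 s running-median debounce on the zone index, and computes time in
#' zone, crossing counts per adjacent-zone boundary, and crossing
#' frequencies per minute.
#'
#' @param tracking data frame with `t`, `x`, `y`.
#' @param arena an [arena_spec()].
#' @param debounce debounce window (s).
#' @return object of class `zone_metrics`: list with `timeline` (per-sample
#'   labels), `time_in_zone` (s, named), `crossings` (data frame `t`,
#'   `from`, `to`), `crossing_counts` (named, per ordered boundary pair),
#'   `crossing_freq_per_min`.
#' @export
zone_metrics <- function(tracking, arena, debounce = 0.2) {
  if (nrow(tracking) == 0) stop("tracking is empty")
  labels <- assign_zone(tracking$x, tracking$y, arena)
  zi <- match(labels, arena$zone_labels)
  dt <- stats::median(diff(tracking$t))
  if (is.na(dt)) dt <- 0
  k <- max(1L, round(debounce / max(dt, 1e-9)))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > 1L && length(zi) > k) zi <- as.integer(stats::runmed(zi, k))
  labels <- arena$zone_labels[zi]
  duration <- nrow(tracking) * dt
  time_in_zone <- vapply(arena$zone_labels,
                         function(z) sum(labels == z) * dt, numeric(1))
  ch <- which(diff(zi) != 0)
  crossings <- data.frame(t = tracking$t[ch + 1L],
                          from = arena$zone_labels[zi[ch]],
                          to = arena$zone_labels[zi[ch + 1L]])
  pair <- paste(crossings$from, crossings$to, sep = "->")
  counts <- table(pair)
  structure(list(timeline = labels, time_in_zone = time_in_zone,
                 crossings = crossings,
                 crossing_counts = counts,
                 crossing_freq_per_min = counts / (duration / 60),
                 duration = duration),
            class = "zone_metrics")
}

#' Segment an LFP by arena zone and walking state
#'
#' Divides the LFP into overlapping windows (3 s length, 2.5 s overlap),
#' labels each window with the majority zone and mean running speed of the
#' concurrent tracking, and optionally keeps only windows fully contained
#' in a continuous walking bout (speed >= `walk_speed` for at least
#' `min_walk` seconds).
#'
#' @param lfp numeric vector (one channel).
#' @param fs LFP sampling rate (Hz).
#' @param tracking data frame with `t`, `x`, `y`; must span the LFP.
#' @param arena an [arena_spec()].
#' @param window,overlap window length and overlap (s).
#' @param walking_filter logical; apply the continuous-walking filter.
#' @param min_walk minimum walking-bout duration (s).
#' @param walk_speed walking speed threshold (cm/s).
#' @param min_purity minimum fraction of tracking samples in the majority
#'   zone for a window to be kept (1 keeps only windows lying entirely in
#'   one zone; windows spanning a zone change are ambiguous).
#' @return object of class `zone_segments`: data frame with `start` (s),
#'   `zone`, `mean_speed`, `purity`, `walking`, plus attributes `fs`,
#'   `window`.
#' @export
segment_lfp_by_zone <- function(lfp, fs, tracking, arena, window = 3,
                                overlap = 2.5, walking_filter = FALSE,
                                min_walk = 2, walk_speed = 5,
                                min_purity = 1) {
  lfp_dur <- length(lfp) / fs
  track_dur <- max(tracking$t) + stats::median(diff(tracking$t))
  if (abs(lfp_dur - track_dur) > window) {
    stop("LFP and tracking streams are misaligned (duration mismatch)")
  }
  L <- round(window * fs)
  step <- max(1L, round((window - overlap) * fs))
  starts <- seq(1L, length(lfp) - L + 1L, by = step)
  zm_labels <- assign_zone(tracking$x, tracking$y, arena)
  sp <- tracking_speed(tracking)
  # walking bouts on the tracking time base
  walking <- sp$speed >= walk_speed
  r <- rle(walking)
  ends <- cumsum(r$lengths)
  bout_ok <- rep(FALSE, length(walking))
  dt <- stats::median(diff(tracking$t))
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] * dt >= min_walk) {
      bout_ok[(ends[i] - r$lengths[i] + 1L):ends[i]] <- TRUE
    }
  }
  rows <- lapply(starts, function(s0) {
    t0 <- (s0 - 1L) / fs; t1 <- t0 + window
    sel <- tracking$t >= t0 & tracking$t < t1
    if (!any(sel)) return(NULL)
    zone <- majority_label(zm_labels[sel])
    data.frame(start = t0, zone = zone,
               mean_speed = mean(sp$speed[sel]),
               purity = mean(zm_labels[sel] == zone),
               walking = all(bout_ok[sel]))
  })
  out <- do.call(rbind, rows)
  out <- out[out$purity >= min_purity - 1e-9, , drop = FALSE]
  if (walking_filter) out <- out[out$walking, , drop = FALSE]
  attr(out, "fs") <- fs
  attr(out, "window") <- window
  class(out) <- c("zone_segments", "data.frame")
  out
}

#' Per-zone averaged power spectra from zone segments
#'
#' Averages single-window Hamming periodograms of the LFP windows assigned
#' to each zone, yielding one `power_spectrum` per zone.
#'
#' @param lfp numeric vector used to build `segments`.
#' @param segments a `zone_segments` data frame from
#'   [segment_lfp_by_zone()].
#' @param min_segments zones with fewer windows than this are dropped.
#' @return named list of `power_spectrum` objects.
#' @export
zone_psd <- function(lfp, segments, min_segments = 3) {
  fs <- attr(segments, "fs")
  window <- attr(segments, "window")
  L <- round(window * fs)
  w <- as.numeric(signal::hamming(L))
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  mult <- rep(2, nf); mult[1L] <- 1
  if (L %% 2L == 0L) mult[nf] <- 1
  freqs <- (seq_len(nf) - 1L) * fs / L
  out <- list()
  for (z in unique(segments$zone)) {
    st <- segments$start[segments$zone == z]
    if (length(st) < min_segments) next
    acc <- numeric(nf)
    for (t0 in st) {
      s0 <- round(t0 * fs) + 1L
      seg <- lfp[s0:(s0 + L - 1L)]
      seg <- (seg - mean(seg)) * w
      acc <- acc + (Mod(stats::fft(seg)[seq_len(nf)])^2) / (fs * U) * mult
    }
    out[[z]] <- as_power_spectrum(freqs, acc / length(st), window,
                                  window - 0.5, length(st))
  }
  out
}
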