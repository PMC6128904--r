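#' Closed-loop controller configuration
#'
#' Parameters of the real-time theta2 trigger: a 30 s baseline, a 6-8 Hz
#' detection band, 1/8 s signal chunks, a band-power threshold of 2.5 times
#' baseline, and a 5 cm/s speed criterion applied as `speed > 5` in movement
#' mode or `speed < 5` in immobility mode. All comparisons are strict.
#'
#' @param baseline_duration baseline length (s).
#' @param band detection band (Hz).
#' @param chunk_length chunk duration (s).
#' @param threshold band-power ratio over baseline required to trigger.
#' @param speed_criterion speed criterion (cm/s).
#' @param mode `"movement"` or `"immobility"`.
#' @param pad_to chunk periodogram zero-padding length (s); a 0.125 s chunk
#'   alone gives only 8 Hz resolution, so the band-power readout
#'   interpolates on a padded grid.
#' @return object of class `controller_config`.
#' @export
controller_config <- function(baseline_duration = 30, band = c(6, 8),
                              chunk_length = 0.125, threshold = 2.5,
                              speed_criterion = 5,
                              mode = c("movement", "immobility"),
                              pad_to = 1) {
  mode <- match.arg(mode)
  if (threshold <= 0) stop("threshold must be positive")
  if (chunk_length <= 0) stop("chunk_length must be positive")
  structure(list(baseline_duration = baseline_duration, band = band,
                 chunk_length = chunk_length, threshold = threshold,
                 speed_criterion = speed_criterion, mode = mode,
                 pad_to = pad_to),
            class = "controller_config")
}

# single-chunk band power: rectangular-window periodogram, zero-padded,
# summed over bins inside the band (the chunk-level estimator of the
# controller; identical for baseline and online chunks)
chunk_band_power <- function(chunk, fs, band, pad_to = 1) {
  n <- length(chunk)
  nfft <- max(n, round(pad_to * fs))
  X <- stats::fft(c(chunk - mean(chunk), numeric(nfft - n)))
  nf <- floor(nfft / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * fs / nfft
  P <- (Mod(X[seq_len(nf)])^2) / (fs * n)
  mult <- rep(2, nf); mult[1L] <- 1
  if (nfft %% 2L == 0L) mult[nf] <- 1
  sel <- freqs >= band[1] & freqs <= band[2]
  sum(P[sel] * mult[sel]) * fs / nfft
}

#' Baseline band power for the closed-loop trigger
#'
#' Splits the baseline signal into controller chunks and averages their
#' band power, using exactly the chunk-level estimator of [cl_step()].
#'
#' @param signal baseline LFP (at least `baseline_duration` long).
#' @param fs sampling rate (Hz).
#' @param config a [controller_config()].
#' @return scalar mean baseline band power.
#' @export
compute_baseline <- function(signal, fs, config = controller_config()) {
  need <- round(config$baseline_duration * fs)
  if (length(signal) < need) stop("baseline signal shorter than baseline_duration")
  signal <- signal[seq_len(need)]
  L <- round(config$chunk_length * fs)
  starts <- seq(1L, need - L + 1L, by = L)
  bp <- vapply(starts, function(s0) {
    chunk_band_power(signal[s0:(s0 + L - 1L)], fs, config$band, config$pad_to)
  }, numeric(1))
  out <- mean(bp)
  if (out <= 0) stop("baseline band power is zero; invalid baseline")
  out
}

#' One closed-loop controller step
#'
#' Evaluates one signal chunk: the power gate passes when the chunk's band
#' power strictly exceeds `threshold` times the baseline power; the speed
#' gate passes when speed is strictly above (movement mode) or strictly
#' below (immobility mode) the speed criterion. The laser fires only when
#' both gates pass, and only for this chunk.
#'
#' @param chunk LFP chunk of exactly `chunk_length` seconds.
#' @param speed chunk speed (cm/s).
#' @param baseline_power output of [compute_baseline()].
#' @param fs sampling rate (Hz).
#' @param config a [controller_config()].
#' @param t_start chunk start time (s), carried into the record.
#' @return one-row data frame: `t_start`, `band_power`, `power_ratio`,
#'   `speed`, `power_gate`, `speed_gate`, `laser_on`.
#' @export
cl_step <- function(chunk, speed, baseline_power, fs,
                    config = controller_config(), t_start = NA_real_) {
  if (length(chunk) != round(config$chunk_length * fs)) {
    stop("chunk length does not match the configured chunk_length")
  }
  bp <- chunk_band_power(chunk, fs, config$band, config$pad_to)
  ratio <- bp / baseline_power
  power_gate <- ratio > config$threshold
  speed_gate <- if (config$mode == "movement") speed > config$speed_criterion
                else speed < config$speed_criterion
  data.frame(t_start = t_start, band_power = bp, power_ratio = ratio,
             speed = speed, power_gate = power_gate, speed_gate = speed_gate,
             laser_on = power_gate && speed_gate)
}

#' Replay the closed-loop controller over a recorded session
#'
#' Computes the baseline from the first `baseline_duration` seconds of the
#' chosen channel, then steps chunk by chunk through the remainder of the
#' session, deriving per-chunk speed from the tracking centroid displacement
#' across the chunk. Deterministic: identical inputs give identical logs.
#'
#' @param session a `session_data` (or any list with `lfp`, `fs`,
#'   `tracking`).
#' @param config a [controller_config()].
#' @param channel LFP channel used by the detector.
#' @return object of class `trigger_log`: data frame of per-chunk records
#'   (see [cl_step()]) with the config as attribute.
#' @export
replay <- function(session, config = controller_config(), channel = 1L) {
  lfp <- session$lfp[channel, ]
  fs <- session$fs
  need <- round(config$baseline_duration * fs)
  if (length(lfp) <= need) stop("session shorter than the baseline period")
  base_p <- compute_baseline(lfp, fs, config)
  L <- round(config$chunk_length * fs)
  starts <- seq(need + 1L, length(lfp) - L + 1L, by = L)
  tr <- session$tracking
  recs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    s0 <- starts[k]
    t0 <- (s0 - 1L) / fs
    t1 <- t0 + config$chunk_length
    # centroid displacement across the chunk / chunk duration
    p0 <- c(stats::approx(tr$t, tr$x, t0, rule = 2)$y,
            stats::approx(tr$t, tr$y, t0, rule = 2)$y)
    p1 <- c(stats::approx(tr$t, tr$x, t1, rule = 2)$y,
            stats::approx(tr$t, tr$y, t1, rule = 2)$y)
    speed <- sqrt(sum((p1 - p0)^2)) / config$chunk_length
    recs[[k]] <- cl_step(lfp[s0:(s0 + L - 1L)], speed, base_p, fs, config,
                         t_start = t0)
  }
  log <- do.call(rbind, recs)
  attr(log, "config") <- config
  attr(log, "baseline_power") <- base_p
  class(log) <- c("trigger_log", "data.frame")
  log
}

#' Validate a trigger log against known theta2-on intervals
#'
#' Chunk-level confusion of the laser decision against ground-truth
#' intervals, plus the median latency (in chunks) from each burst onset to
#' the first trigger within that burst.
#'
#' @param log a `trigger_log`.
#' @param intervals data frame with `start`, `end` (s) of true theta2
#'   epochs.
#' @return list with `sensitivity`, `specificity`, `median_latency_chunks`,
#'   and the confusion counts.
#' @export
validate_triggers <- function(log, intervals) {
  if (nrow(log) == 0) stop("empty trigger log")
  truth <- rep(FALSE, nrow(log))
  for (k in seq_len(nrow(intervals))) {
    truth <- truth | (log$t_start >= intervals$start[k] &
                      log$t_start < intervals$end[k])
  }
  tp <- sum(truth & log$laser_on); fn <- sum(truth & !log$laser_on)
  fp <- sum(!truth & log$laser_on); tn <- sum(!truth & !log$laser_on)
  lat <- vapply(seq_len(nrow(intervals)), function(k) {
    in_burst <- which(log$t_start >= intervals$start[k] &
                      log$t_start < intervals$end[k])
    hit <- in_burst[log$laser_on[in_burst]]
    if (length(hit) == 0) NA_real_ else hit[1] - in_burst[1]
  }, numeric(1))
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       median_latency_chunks = stats::median(lat, na.rm = TRUE),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' @export
print.trigger_log <- function(x, ...) {
  cat(sprintf("Trigger log: %d chunks, %d laser-on (%.1f%%)\n",
              nrow(x), sum(x$laser_on), 100 * mean(x$laser_on)))
  invisible(as.data.frame(x))
}
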