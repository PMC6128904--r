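#' One-dimensional current-source density
#'
#' Standard second-spatial-difference estimator across equally spaced
#' laminar channels:
#' `csd_i = -(V_{i-1} - 2 V_i + V_{i+1}) / spacing^2`,
#' with positive values plotted as current sources. The two edge channels
#' are dropped unless Vaknin padding is requested (edge channels duplicated
#' before differencing). Optional spatial (Hamming) smoothing across
#' channels is off by default.
#'
#' @param laminar_lfp channels x samples numeric matrix (mV).
#' @param spacing inter-channel spacing (µm).
#' @param vaknin logical; duplicate edge channels so all channels are
#'   retained.
#' @param smooth logical; apply a three-point spatial Hamming smoother to
#'   the LFP before differencing.
#' @return object of class `csd_map`: list with `csd` (matrix, positive =
#'   source), `depths` (µm of retained channels, first input channel at 0),
#'   `spacing`, `channels` (input row indices retained).
#' @export
compute_csd <- function(laminar_lfp, spacing, vaknin = FALSE, smooth = FALSE) {
  if (!is.matrix(laminar_lfp)) laminar_lfp <- as.matrix(laminar_lfp)
  if (spacing <= 0) stop("spacing must be positive")
  nch <- nrow(laminar_lfp)
  if (nch < 3) stop("at least 3 channels are required")
  V <- laminar_lfp
  if (smooth) {
    w <- c(0.23, 0.54, 0.23)
    Vs <- V
    for (i in 2:(nch - 1)) {
      Vs[i, ] <- w[1] * V[i - 1, ] + w[2] * V[i, ] + w[3] * V[i + 1, ]
    }
    V <- Vs
  }
  if (vaknin) {
    V <- rbind(V[1, , drop = FALSE], V, V[nch, , drop = FALSE])
    keep <- seq_len(nch)
  } else {
    keep <- 2:(nch - 1)
  }
  inner <- 2:(nrow(V) - 1)
  csd <- -(V[inner - 1, , drop = FALSE] - 2 * V[inner, , drop = FALSE] +
             V[inner + 1, , drop = FALSE]) / spacing^2
  structure(list(csd = csd, depths = (keep - 1) * spacing, spacing = spacing,
                 channels = keep),
            class = "csd_map")
}

#' Band-limited CSD amplitude per channel
#'
#' RMS of the band-filtered CSD trace of every retained channel; used to
#' locate the dominant source/sink layer (e.g. the perisomatic theta source).
#'
#' @param csdmap a `csd_map` from [compute_csd()].
#' @param band filter band (Hz), e.g. `c(4, 12)` for theta.
#' @param fs sampling rate of the CSD traces (Hz).
#' @return numeric vector of per-channel RMS amplitudes, named by depth.
#' @export
band_csd_amplitude <- function(csdmap, band, fs) {
  stopifnot(inherits(csdmap, "csd_map"))
  amps <- apply(csdmap$csd, 1, function(row) {
    if (all(row == 0)) return(0)
    sqrt(mean(fir_bandpass(row, fs, band[1], band[2])^2))
  })
  names(amps) <- csdmap$depths
  amps
}

#' @export
print.csd_map <- function(x, ...) {
  cat(sprintf("CSD map: %d channels x %d samples, spacing %g um (positive = source)\n",
              nrow(x$csd), ncol(x$csd), x$spacing))
  invisible(x)
}
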