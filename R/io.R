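#' Write a session to disk
#'
#' Serializes a `session_data` object with R's native serialization
#' (lossless on all arrays and metadata); [read_session()] is its exact
#' inverse. Tracking, stimulation epochs and trigger logs can additionally
#' be exported as plain CSV with [export_tracking_csv()] and friends.
#'
#' @param session a `session_data`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_data"))
  saveRDS(session, path)
  invisible(path)
}

#' Read a session from disk
#'
#' @param path file written by [write_session()].
#' @return the `session_data` object.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("session file not found: ", path)
  session <- readRDS(path)
  required <- c("lfp", "fs", "tracking", "spikes", "stim_epochs", "config")
  missing <- setdiff(required, names(session))
  if (length(missing)) {
    stop("session container is missing dataset(s): ",
         paste(missing, collapse = ", "))
  }
  session
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Export tracking as CSV
#'
#' Columns `t,x,y`, written with 17 significant digits so that re-import
#' reproduces the doubles exactly.
#'
#' @param tracking data frame with `t`, `x`, `y`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_tracking_csv <- function(tracking, path) {
  df <- data.frame(t = fmt_num(tracking$t), x = fmt_num(tracking$x),
                   y = fmt_num(tracking$y))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import tracking from CSV
#'
#' @param path CSV with columns `t,x,y`.
#' @return data frame of class `tracking`.
#' @export
import_tracking_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("t", "x", "y") %in% names(df))) {
    stop("tracking CSV must have columns t,x,y")
  }
  class(df) <- c("tracking", "data.frame")
  df
}

#' Export stimulation epochs as CSV
#'
#' Columns `start,end,freq`.
#'
#' @param stim_epochs data frame with `start`, `end`, `freq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_stim_csv <- function(stim_epochs, path) {
  utils::write.csv(stim_epochs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trigger log as CSV
#'
#' @param log a `trigger_log` from [replay()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_trigger_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Provenance block for reproducible runs
#'
#' @param config any serializable configuration object.
#' @param seed integer seed of the run.
#' @return list with `config_hash`, `seed`, `package_version`, `timestamp`.
#' @export
provenance <- function(config, seed) {
  raw <- serialize(config, NULL)
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  list(config_hash = sprintf("%08x", h), seed = seed,
       package_version = as.character(utils::packageVersion("thetawave")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}
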