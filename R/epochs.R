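#' Epoched sensor-array container
#'
#' Holds outcome-locked EEG epochs as a trials x channels x samples array
#' together with the sampling rate and the time of the first sample
#' relative to outcome onset.
#'
#' @param data Numeric array, trials x channels x samples, no missing
#'   values.
#' @param sfreq Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds relative to outcome onset
#'   (negative for pre-outcome baseline).
#' @param channel_names Optional channel identifiers.
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, sfreq, t0, channel_names = NULL) {
  stopifnot(length(dim(data)) == 3, sfreq > 0)
  if (anyNA(data)) stop("epochs must not contain missing values")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2]))
  stopifnot(length(channel_names) == dim(data)[2])
  structure(list(data = data, sfreq = sfreq, t0 = t0,
                 channel_names = channel_names),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  tms <- epoch_times(x)
  cat("Epoch array:", d[1], "trials x", d[2], "channels x", d[3], "samples\n")
  cat("  sfreq:", x$sfreq, "Hz | span:", round(tms[1] * 1000), "to",
      round(tms[length(tms)] * 1000), "ms\n")
  invisible(x)
}

#' Sample times of an epoch array
#'
#' @param epochs An `epoch_array`.
#' @return Numeric vector of sample times in seconds.
#' @export
epoch_times <- function(epochs) {
  epochs$t0 + (seq_len(dim(epochs$data)[3]) - 1L) / epochs$sfreq
}

#' Per-trial window-averaged sensor vectors
#'
#' Averages each trial's sensor data over the samples whose times fall in
#' \[center - width/2, center + width/2) (half-open upper bound).
#'
#' @param epochs An `epoch_array`.
#' @param center Window center in ms relative to outcome onset.
#' @param width Window width in ms.
#' @return Trials x channels matrix.
#' @export
window_average <- function(epochs, center, width = 60) {
  tms <- epoch_times(epochs) * 1000
  lo <- center - width / 2
  hi <- center + width / 2
  dt <- 1000 / epochs$sfreq
  if (lo < tms[1] - dt / 2 || hi > tms[length(tms)] + dt)
    stop("window [", lo, ", ", hi, "] ms lies outside the epoch")
  eps <- dt * 1e-6                     # guard against float jitter in tms
  sel <- which(tms >= lo - eps & tms < hi - eps)
  if (length(sel) == 0) stop("window contains no samples")
  if (length(sel) == 1) return(epochs$data[, , sel, drop = TRUE])
  apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
}

#' Sliding-window specification
#'
#' @param centers Window centers in ms (default -100 to 600 in 10 ms
#'   steps).
#' @param width Window width in ms (default 60).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(centers = seq(-100, 600, by = 10), width = 60) {
  structure(list(centers = centers, width = width), class = "window_spec")
}

#' Write/read an epoch array as delimited text plus a JSON sidecar
#'
#' The data file holds one row per (trial, channel) with samples as
#' columns; the sidecar records dimensions, sampling rate, epoch start and
#' channel names.
#'
#' @param epochs An `epoch_array`.
#' @param path Base path; `<path>.tsv` and `<path>.json` are written.
#' @return `read_epochs()` returns an `epoch_array`.
#' @export
write_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  utils::write.table(flat, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(n_trials = d[1], n_channels = d[2], n_samples = d[3],
               sfreq = epochs$sfreq, t0 = epochs$t0,
               channel_names = epochs$channel_names)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  flat <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  arr <- aperm(array(t(flat), dim = c(meta$n_samples, meta$n_channels,
                                      meta$n_trials)), c(3, 2, 1))
  epoch_array(arr, meta$sfreq, meta$t0, meta$channel_names)
}
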