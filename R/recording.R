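#' Continuous EEG recordings and epoch sets
#'
#' An `eeg_recording` holds a channels x samples signal matrix in microvolts,
#' its sampling rate, ordered channel labels, and event markers (press
#' events). An `eeg_epochs` object holds press-locked trials as a
#' trials x channels x samples array plus per-trial metadata.
#'
#' @name recording
NULL

#' Construct an EEG recording
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels, one per signal row.
#' @param events Tibble/data frame with columns `sample` (1-based index into
#'   the signal) and `code` (marker string); may have zero rows.
#' @param log Optional list of per-stage processing log records.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(signal, fs, labels, events = NULL, log = list()) {
  signal <- as.matrix(signal)
  if (is.null(events)) {
    events <- tibble::tibble(sample = integer(), code = character())
  }
  events <- tibble::as_tibble(events)
  if (length(labels) != nrow(signal)) {
    abort(sprintf("labels length (%d) != channel count (%d)", length(labels), nrow(signal)))
  }
  if (fs <= 0) abort("fs must be positive")
  if (nrow(events) > 0 &&
      (any(events$sample < 1) || any(events$sample > ncol(signal)))) {
    abort("event sample index outside the recorded signal")
  }
  structure(
    list(signal = signal, fs = fs, labels = as.character(labels),
         events = events, log = log),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, nrow(x$events)))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$signal)

rec_log <- function(rec, stage, ...) {
  rec$log[[length(rec$log) + 1L]] <- c(list(stage = stage,
                                            n_channels = nrow(rec$signal),
                                            n_samples = ncol(rec$signal),
                                            fs = rec$fs),
                                       list(...))
  rec
}

#' Construct an epoch set
#'
#' @param data Numeric array, trials x channels x samples, microvolts.
#' @param fs Sampling rate in Hz.
#' @param window Epoch window `c(start, end)` in seconds relative to the press,
#'   half-open: samples cover `[start, end)`.
#' @param labels Channel labels.
#' @param info Per-trial metadata tibble (at least `trial`; typically also
#'   `subject`, `hand`, `event_sample`).
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, fs, window, labels, info) {
  stopifnot(length(dim(data)) == 3)
  info <- tibble::as_tibble(info)
  if (dim(data)[1] != nrow(info)) abort("info rows != number of trials")
  if (dim(data)[2] != length(labels)) abort("labels length != channel dimension")
  expected <- round(fs * (window[2] - window[1]))
  if (dim(data)[3] != expected) {
    abort(sprintf("epoch length %d != round(fs * window) = %d", dim(data)[3], expected))
  }
  structure(
    list(data = data, fs = fs, window = window,
         labels = as.character(labels), info = info),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Epoch sample times
#'
#' @param epochs An `eeg_epochs` object.
#' @return Numeric vector of sample times in seconds relative to the press.
#' @export
epoch_times <- function(epochs) {
  epochs$window[1] + (seq_len(dim(epochs$data)[3]) - 1L) / epochs$fs
}
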