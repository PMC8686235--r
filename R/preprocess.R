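#' Preprocessing chain
#'
#' The fixed preprocessing order is: [downsample()] (1000 -> 200 Hz) ->
#' [rereference_car()] (common average reference) -> [bandpass_filter()]
#' (0.5-50.5 Hz zero-phase 3rd-order Butterworth) -> [remove_artifacts()]
#' (ICA) -> [epoch_trials()] (press-locked, \eqn{[-0.5, 0.5)} s).
#' [preprocess_recording()] runs the whole chain and logs every stage.
#'
#' @name preprocess
NULL

# Zero-phase filtering of every channel row: the squared Butterworth
# magnitude response (what a forward-backward pass applies) multiplied onto
# the spectrum of the zero-padded signal. Identical transfer function to
# filtfilt, applied to all channels in one FFT pass; the pad absorbs the
# filter's ring-out so there is no circular leakage into the record.
.filtfilt_rows <- function(signal, filt, pad_s = 4, fs = NULL) {
  n <- ncol(signal)
  pad <- if (is.null(fs)) 4000L else as.integer(round(pad_s * fs))
  n2 <- stats::nextn(n + pad, c(2, 3, 5))
  w <- 2 * pi * (seq_len(n2) - 1) / n2
  E <- exp(-1i * outer(w, seq_along(filt$b) - 1))
  H <- as.vector(E %*% filt$b) / as.vector(E[, seq_along(filt$a), drop = FALSE] %*% filt$a)
  mag2 <- Mod(H)^2
  X <- mvfft(t(cbind(signal, matrix(0, nrow(signal), n2 - n))))
  out <- Re(mvfft(X * mag2, inverse = TRUE)) / n2
  t(out[seq_len(n), , drop = FALSE])
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (6th-order Butterworth, cutoff
#' 0.4 * `target_fs`) and keeps every k-th sample. Event indices are remapped
#' to the decimated grid.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target sampling rate; `rec$fs` must be an integer multiple.
#' @return Downsampled `eeg_recording`.
#' @export
downsample <- function(rec, target_fs = 200) {
  k <- rec$fs / target_fs
  if (abs(k - round(k)) > 1e-9) {
    abort(sprintf("fs = %g is not an integer multiple of target_fs = %g", rec$fs, target_fs))
  }
  k <- as.integer(round(k))
  if (k == 1L) return(rec_log(rec, "downsample", factor = 1L))
  aa <- signal::butter(6, 0.4 * target_fs / (rec$fs / 2), type = "low")
  filtered <- .filtfilt_rows(rec$signal, aa, fs = rec$fs)
  idx <- seq(1L, ncol(rec$signal), by = k)
  events <- rec$events
  # nearest decimated sample, so the remap is unbiased in time
  if (nrow(events) > 0) {
    events$sample <- pmin(as.integer(round((events$sample - 1L) / k)) + 1L,
                          length(idx))
  }
  out <- eeg_recording(filtered[, idx, drop = FALSE], target_fs, rec$labels,
                       events, rec$log)
  rec_log(out, "downsample", factor = k, cutoff_hz = 0.4 * target_fs)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so the
#' channel mean of the output is exactly zero at every sample.
#'
#' @param rec An `eeg_recording` with at least 2 channels.
#' @return Re-referenced `eeg_recording`.
#' @export
rereference_car <- function(rec) {
  if (nrow(rec$signal) < 2) abort("common average reference needs at least 2 channels")
  out <- rec
  out$signal <- sweep(rec$signal, 2, colMeans(rec$signal))
  rec_log(out, "car")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward 3rd-order Butterworth band-pass (effective 6th-order
#' magnitude, zero phase shift) applied to the continuous record so that
#' filter transients fall outside the analysis windows.
#'
#' @param rec An `eeg_recording`.
#' @param lo,hi Band edges in Hz; `hi` must be below Nyquist.
#' @param order Filter order (per pass).
#' @return Filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, lo = 0.5, hi = 50.5, order = 3) {
  if (hi >= rec$fs / 2) {
    abort(sprintf("upper edge %g Hz is not below Nyquist (%g Hz)", hi, rec$fs / 2))
  }
  filt <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  out <- rec
  out$signal <- .filtfilt_rows(rec$signal, filt, fs = rec$fs)
  rec_log(out, "bandpass", lo_hz = lo, hi_hz = hi, order = order, zero_phase = TRUE)
}

#' Remove physiological artifacts
#'
#' For `method = "ica_auto"`: decomposes the recording with FastICA, flags
#' components automatically — a frontal-dominant topography whose power is
#' dominated by the 0.5-4 Hz range (ocular), or an absolute excess-kurtosis
#' z-score above `kurtosis_z` across components (transient artifacts) — and
#' subtracts the flagged components' contribution from the signal.
#' `method = "none"` returns the input unchanged.
#'
#' @param rec An `eeg_recording`.
#' @param method `"ica_auto"` or `"none"`.
#' @param kurtosis_z Kurtosis z-score threshold for the transient criterion.
#' @param delta_fraction Minimum fraction of component power below 4 Hz for
#'   the ocular criterion.
#' @param kurt_min Absolute excess-kurtosis floor for the transient flag.
#' @param frontal_ratio Frontal concentration threshold for the ocular flag.
#' @param seed Seed for the ICA initialization.
#' @return An `eeg_recording`; the number of removed components is recorded in
#'   the processing log and in the `n_components_removed` attribute.
#' @export
remove_artifacts <- function(rec, method = c("ica_auto", "none"),
                             kurtosis_z = 3, delta_fraction = 0.5,
                             kurt_min = 10, frontal_ratio = 2, seed = 1) {
  method <- match.arg(method)
  if (method == "none") {
    out <- rec_log(rec, "artifacts", method = "none", n_components_removed = 0L)
    attr(out, "n_components_removed") <- 0L
    return(out)
  }
  n_ch <- nrow(rec$signal)
  if (ncol(rec$signal) < 20 * n_ch^2) {
    warn(sprintf("only %d samples for %d channels; ICA decomposition may be unstable",
                 ncol(rec$signal), n_ch))
  }
  dec <- fast_ica(rec$signal, seed = seed)
  flags <- flag_ica_components(dec, rec$labels, rec$fs,
                               kurtosis_z = kurtosis_z,
                               delta_fraction = delta_fraction,
                               kurt_min = kurt_min,
                               frontal_ratio = frontal_ratio)
  removed <- which(flags$flagged)
  out <- rec
  if (length(removed) > 0) {
    # subtract the flagged components' contribution from the original signal,
    # leaving everything outside the decomposed subspace untouched
    out$signal <- rec$signal - dec$mixing[, removed, drop = FALSE] %*%
      dec$sources[removed, , drop = FALSE]
  }
  out <- rec_log(out, "artifacts", method = "ica_auto",
                 n_components_removed = length(removed),
                 removed = removed, reasons = flags$reason[removed])
  attr(out, "n_components_removed") <- length(removed)
  out
}

#' Extract press-locked epochs
#'
#' Cuts one epoch per event with a half-open window: at event sample t the
#' epoch covers samples `t + fs*window[1]` up to (but excluding)
#' `t + fs*window[2]`, i.e. exactly `round(fs * diff(window))` samples (200 at
#' 200 Hz for the default 1-s window, giving 1 Hz spectral resolution
#' downstream). Events whose window would cross the record edges are dropped
#' and reported in the `dropped_events` attribute.
#'
#' @param rec An `eeg_recording` (typically at 200 Hz).
#' @param window Window in seconds relative to the press, default `c(-0.5, 0.5)`.
#' @param subject,hand Optional metadata stamped on every trial.
#' @return An `eeg_epochs` object.
#' @export
epoch_trials <- function(rec, window = c(-0.5, 0.5), subject = NA_character_,
                         hand = NA_character_) {
  if (nrow(rec$events) == 0) abort("recording has no events to epoch")
  n <- round(rec$fs * (window[2] - window[1]))
  off0 <- round(rec$fs * window[1])
  starts <- rec$events$sample + off0
  usable <- starts >= 1 & (starts + n - 1) <= ncol(rec$signal)
  if (!any(usable)) abort("no usable events: all epochs cross the record edges")
  kept <- which(usable)
  data <- array(0, dim = c(length(kept), nrow(rec$signal), n))
  for (i in seq_along(kept)) {
    s <- starts[kept[i]]
    data[i, , ] <- rec$signal[, s:(s + n - 1L)]
  }
  info <- tibble::tibble(
    subject = subject, hand = hand, trial = seq_along(kept),
    event_sample = rec$events$sample[kept]
  )
  ep <- eeg_epochs(data, rec$fs, window, rec$labels, info)
  attr(ep, "dropped_events") <- which(!usable)
  ep
}

#' Run the full preprocessing chain
#'
#' downsample -> common average reference -> band-pass -> artifact removal ->
#' epoching, in that fixed order.
#'
#' @param rec Raw `eeg_recording` (e.g. 63 channels at 1000 Hz).
#' @param target_fs Sampling rate after decimation.
#' @param lo,hi Band-pass edges in Hz.
#' @param artifacts Artifact-removal method, `"none"` or `"ica_auto"`.
#' @param window Epoch window in seconds.
#' @param subject,hand Metadata stamped on the trials.
#' @param ... Further arguments passed to [remove_artifacts()].
#' @return An `eeg_epochs` object; the stage log is in the `log` attribute.
#' @export
preprocess_recording <- function(rec, target_fs = 200, lo = 0.5, hi = 50.5,
                                 artifacts = "none", window = c(-0.5, 0.5),
                                 subject = NA_character_, hand = NA_character_,
                                 ...) {
  rec <- downsample(rec, target_fs)
  rec <- rereference_car(rec)
  rec <- bandpass_filter(rec, lo, hi)
  rec <- remove_artifacts(rec, artifacts, ...)
  ep <- epoch_trials(rec, window, subject = subject, hand = hand)
  attr(ep, "log") <- rec$log
  ep
}
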