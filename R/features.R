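#' Frequency bands
#'
#' The six canonical analysis bands. Band membership of a spectral bin is
#' half-open, `[lo, hi)`: the shared edges at 4, 8, 13 and 30 Hz belong to the
#' upper band only, so delta..gamma tile 1-49 Hz with no overlap, and `full`
#' covers 1-49 Hz.
#'
#' @return Tibble with columns `band`, `lo`, `hi` (Hz).
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma", "full"),
    lo   = c(1, 4, 8, 13, 30, 1),
    hi   = c(4, 8, 13, 30, 50, 50)
  )
}

.band_row <- function(band) {
  bands <- eeg_bands()
  if (is.character(band)) {
    if (!band %in% bands$band) {
      abort(sprintf("unknown band '%s'; known bands: %s",
                    band, paste(bands$band, collapse = ", ")))
    }
    bands[bands$band == band, ]
  } else {
    tibble::as_tibble(band)
  }
}

#' One-sided power spectrum of a single epoch
#'
#' Rectangular-window FFT power spectrum of a 1-s epoch. With N samples at
#' `fs = N` Hz the bins fall on integer frequencies 0..N/2 Hz (1 Hz
#' resolution). Normalization: `P_0 = |X_0|^2 / N^2`,
#' `P_k = 2 |X_k|^2 / N^2` for `0 < k < N/2`, `P_{N/2} = |X_{N/2}|^2 / N^2`,
#' so a unit-amplitude sinusoid on an integer bin yields power 0.5 there and
#' the one-sided sum equals the mean square of the series (Parseval).
#'
#' @param trial Channels x N matrix (or length-N vector) in microvolts.
#' @param fs Sampling rate; must equal N (the 1-s, 1-Hz-resolution contract).
#' @return Channels x (N/2 + 1) matrix of power (microvolts^2); columns are
#'   frequencies `0:(N/2)` Hz (in the `freqs` attribute).
#' @export
psd_epoch <- function(trial, fs = 200) {
  if (is.null(dim(trial))) trial <- matrix(trial, nrow = 1)
  n <- ncol(trial)
  if (n != fs) {
    abort(sprintf("epoch length %d != fs %g: the 1 Hz resolution contract requires a 1-s epoch", n, fs))
  }
  X <- t(mvfft(t(trial)))
  half <- n / 2
  P <- Mod(X[, 1:(half + 1), drop = FALSE])^2 / n^2
  P[, 2:half] <- 2 * P[, 2:half]
  structure(P, freqs = 0:half, dimnames = list(rownames(trial), NULL))
}

#' Power spectra for every trial of an epoch set
#'
#' @param epochs An `eeg_epochs` object with 1-s trials.
#' @return Trials x channels x frequencies array with a `freqs` attribute.
#' @export
psd_epochs <- function(epochs) {
  dims <- dim(epochs$data)
  n <- dims[3]
  half <- n / 2
  out <- array(0, dim = c(dims[1], dims[2], half + 1))
  for (i in seq_len(dims[1])) {
    out[i, , ] <- psd_epoch(epochs$data[i, , , drop = TRUE], fs = epochs$fs)
  }
  structure(out, freqs = 0:half,
            dimnames = list(NULL, epochs$labels, NULL))
}

#' Band-averaged power
#'
#' Arithmetic mean of the spectral power over the integer-frequency bins in
#' `[lo, hi)` (half-open, see [eeg_bands()]).
#'
#' @param P Power spectrum: vector, channels x freqs matrix, or a
#'   trials x channels x freqs array from [psd_epochs()]; must carry a
#'   `freqs` attribute (as produced by [psd_epoch()]).
#' @param band Band name or a one-row data frame with `lo`, `hi`.
#' @return Scalar, vector, or trials x channels matrix of mean band power.
#' @export
band_power <- function(P, band) {
  b <- .band_row(band)
  freqs <- attr(P, "freqs")
  if (is.null(freqs)) abort("P has no freqs attribute; use psd_epoch()/psd_epochs()")
  bins <- which(freqs >= b$lo & freqs < b$hi)
  if (length(bins) == 0) abort(sprintf("band [%g, %g) contains no spectral bins", b$lo, b$hi))
  nd <- length(dim(P))
  if (is.null(dim(P))) {
    mean(P[bins])
  } else if (nd == 2) {
    rowMeans(P[, bins, drop = FALSE])
  } else {
    apply(P[, , bins, drop = FALSE], c(1, 2), mean)
  }
}

#' Build a band-power feature table
#'
#' One row per trial: metadata (`subject`, `hand`, `trial`), one column of
#' mean band power per channel in the channel set, and the ground-truth
#' hotspot coordinates `x`, `y`, `z` shared by all trials of a subject/hand.
#'
#' @param epochs An `eeg_epochs` object (or a precomputed [psd_epochs()]
#'   array passed via `psd`).
#' @param band Band name or definition row.
#' @param channels Character vector of channel labels to keep (a channel set);
#'   default all channels.
#' @param truths Tibble with `subject`, `hand`, `x`, `y`, `z` giving each
#'   subject/hand's ground-truth hotspot.
#' @param psd Optional trials x channels x freqs array to avoid recomputing
#'   spectra.
#' @return A tibble of class `hotspot_features` with attributes `band` and
#'   `channels`.
#' @export
build_feature_table <- function(epochs, band, channels = NULL, truths = NULL,
                                psd = NULL) {
  b <- .band_row(band)
  if (is.null(psd)) psd <- psd_epochs(epochs)
  labels <- dimnames(psd)[[2]] %||% epochs$labels
  channels <- channels %||% labels
  missing <- setdiff(channels, labels)
  if (length(missing) > 0) {
    abort(paste0("channel(s) not in epochs: ", paste(missing, collapse = ", ")))
  }
  bp <- band_power(psd, b)            # trials x channels
  colnames(bp) <- labels
  X <- bp[, channels, drop = FALSE]
  out <- dplyr::bind_cols(epochs$info, tibble::as_tibble(X))
  if (!is.null(truths)) {
    truths <- tibble::as_tibble(truths)
    key <- c("subject", if ("hand" %in% names(truths)) "hand")
    out <- dplyr::left_join(out, truths[, c(key, "x", "y", "z")], by = key)
    if (anyNA(out[c("x", "y", "z")])) {
      bad <- unique(out$subject[!stats::complete.cases(out[c("x", "y", "z")])])
      abort(paste0("no ground-truth hotspot for subject(s): ", paste(bad, collapse = ", ")))
    }
  }
  structure(out, band = b$band, channels = channels,
            class = c("hotspot_features", class(out)))
}

#' Feature matrix and target matrix of a feature table
#'
#' @param table A `hotspot_features` tibble.
#' @return List with `X` (trials x channels), `y` (trials x 3 or NULL),
#'   `subject`, `channels`.
#' @export
feature_matrices <- function(table) {
  channels <- attr(table, "channels")
  X <- as.matrix(as.data.frame(table)[, channels, drop = FALSE])
  y <- if (all(c("x", "y", "z") %in% names(table))) {
    as.matrix(as.data.frame(table)[, c("x", "y", "z")])
  }
  list(X = X, y = y, subject = table$subject, channels = channels)
}
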