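#' FastICA decomposition of a multichannel signal
#'
#' Symmetric fixed-point FastICA with the tanh contrast function. The signal
#' is centered and whitened by eigendecomposition of the channel covariance;
#' directions with negligible variance (rank lost to the common average
#' reference) are dropped. Iterations use symmetric orthogonalization and are
#' deterministic given the seed.
#'
#' @param signal Channels x samples matrix.
#' @param n_components Number of components to extract. The default
#'   `floor(sqrt(n_samples / 20))` (capped at the channel rank) keeps the
#'   samples-per-parameter ratio of the unmixing estimate near the
#'   20 p^2 rule of thumb; the decomposition then acts on the leading
#'   principal subspace.
#' @param max_iter Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the update of the unmixing matrix.
#' @param rank_tol Relative eigenvalue threshold for rank truncation.
#' @param seed Seed for the random orthonormal initialization.
#' @return List with `sources` (components x samples), `mixing`
#'   (channels x components), `center` (channel means), `converged`, `n_iter`.
#' @export
fast_ica <- function(signal, n_components = NULL, max_iter = 500, tol = 1e-6,
                     rank_tol = 1e-9, seed = 1) {
  X <- as.matrix(signal)
  center <- rowMeans(X)
  Xc <- X - center
  n <- ncol(Xc)
  C <- tcrossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  keep <- which(eg$values > rank_tol * eg$values[1])
  if (is.null(n_components)) n_components <- max(2L, floor(sqrt(n / 20)))
  keep <- keep[seq_len(min(n_components, length(keep)))]
  d <- eg$values[keep]
  E <- eg$vectors[, keep, drop = FALSE]
  K <- diag(1 / sqrt(d), length(d)) %*% t(E)      # whitening: Z = K Xc
  Z <- K %*% Xc
  p <- nrow(Z)

  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  W <- sym_orth(matrix(rnorm(p * p), p, p))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()) else
    rm(".Random.seed", envir = globalenv())

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W_new <- sym_orth(tcrossprod(G, Z) / n - diag(gprime, p) %*% W)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("FastICA did not converge in %d iterations (delta criterion)", max_iter))
  }
  sources <- W %*% Z
  # mixing back to channel space: Xc = E diag(sqrt(d)) t(W) sources
  mixing <- E %*% diag(sqrt(d), length(d)) %*% t(W)
  list(sources = sources, mixing = mixing, center = center,
       converged = converged, n_iter = it)
}

# excess kurtosis of a vector
.excess_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

#' Flag ICA components as artifacts
#'
#' Two automatic criteria replace visual inspection: (1) ocular — the
#' component topography (mixing column) is concentrated on the prefrontal
#' channels (Fp/AF rows carry at least `frontal_ratio` times the mean
#' absolute weight of the remaining channels) and more than
#' `delta_fraction` of the component power lies below 4 Hz; (2) transient —
#' the component's excess kurtosis is both an outlier among components
#' (|z| > `kurtosis_z`) and large in absolute terms (> `kurt_min`).
#'
#' @param dec A [fast_ica()] decomposition.
#' @param labels Channel labels matching the mixing-matrix rows.
#' @param fs Sampling rate of the sources, Hz.
#' @param kurtosis_z,delta_fraction Thresholds (see [remove_artifacts()]).
#' @param frontal_ratio Minimum frontal-to-other mean absolute weight ratio
#'   for the ocular flag.
#' @param kurt_min Absolute excess-kurtosis floor for the transient flag:
#'   a component must be both an outlier among components (z-score) and
#'   strongly super-Gaussian in absolute terms, so that mildly bursty
#'   physiological components are not discarded.
#' @return Tibble with one row per component: `component`, `flagged`, `reason`.
#' @export
flag_ica_components <- function(dec, labels, fs, kurtosis_z = 3,
                                delta_fraction = 0.5, kurt_min = 10,
                                frontal_ratio = 2) {
  p <- nrow(dec$sources)
  frontal <- grepl("^(Fp|AF)", labels)
  n <- ncol(dec$sources)
  n2 <- stats::nextn(n, c(2, 3, 5))
  freqs <- (seq_len(n2) - 1) * fs / n2
  low <- freqs > 0 & freqs < 4 | freqs > fs - 4    # two-sided bins below 4 Hz
  ocular <- logical(p)
  for (i in seq_len(p)) {
    topo <- abs(dec$mixing[, i])
    if (mean(topo[frontal]) < frontal_ratio * mean(topo[!frontal])) next
    spec <- Mod(fft(c(dec$sources[i, ], numeric(n2 - n))))^2
    spec[1] <- 0
    ocular[i] <- sum(spec[low]) / sum(spec) > delta_fraction
  }
  kurt <- apply(dec$sources, 1, .excess_kurtosis)
  kz <- (kurt - mean(kurt)) / sd(kurt)
  transient <- abs(kz) > kurtosis_z & abs(kurt) > kurt_min
  reason <- dplyr::case_when(
    ocular & transient ~ "ocular+transient",
    ocular ~ "ocular",
    transient ~ "transient",
    TRUE ~ ""
  )
  tibble::tibble(component = seq_len(p), flagged = ocular | transient,
                 reason = reason, kurtosis_z = kz)
}
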