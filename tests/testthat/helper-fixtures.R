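# shared fixtures and independent oracles

# brute-force O(N^2) DFT with the package's one-sided power normalization;
# independent of psd_epoch()'s fft path
brute_psd <- function(x) {
  n <- length(x)
  half <- n / 2
  k <- 0:half
  P <- vapply(k, function(kk) {
    re <- sum(x * cos(-2 * pi * kk * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * kk * (0:(n - 1)) / n))
    (re^2 + im^2) / n^2
  }, numeric(1))
  P[k > 0 & k < half] <- 2 * P[k > 0 & k < half]
  structure(P, freqs = k)
}

# textbook sums-of-squares decomposition for one-way repeated measures
brute_rm_anova_F <- function(M) {
  n <- nrow(M); k <- ncol(M)
  grand <- mean(M)
  ss_cond <- n * sum((colMeans(M) - grand)^2)
  ss_subj <- k * sum((rowMeans(M) - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
}

# small multi-sinusoid test recording with press markers
probe_recording <- function(fs = 1000, dur = 12, freqs = c(10), amps = c(1),
                            n_ch = 4, dc = 0, events_at = NULL) {
  t <- (0:(dur * fs - 1)) / fs
  x <- dc + Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  sig <- matrix(rep(x, each = n_ch), nrow = n_ch)
  ev <- if (!is.null(events_at)) {
    tibble::tibble(sample = as.integer(events_at), code = "press")
  }
  eeg_recording(sig, fs, paste0("ch", seq_len(n_ch)), ev)
}

# feature table with fake band powers (no EEG needed) for CV-plan tests
fake_feature_table <- function(n_subjects = 25, n_trials = 30, p = 5, seed = 99) {
  withr::with_seed(seed, {
    subj <- rep(sprintf("S%02d", seq_len(n_subjects)), each = n_trials)
    X <- matrix(rexp(n_subjects * n_trials * p), ncol = p,
                dimnames = list(NULL, paste0("ch", seq_len(p))))
    truths <- tibble::tibble(
      subject = sprintf("S%02d", seq_len(n_subjects)), hand = "right",
      x = rnorm(n_subjects, -5), y = rnorm(n_subjects), z = rnorm(n_subjects, -2)
    )
    tbl <- dplyr::bind_cols(
      tibble::tibble(subject = subj, hand = "right",
                     trial = rep(seq_len(n_trials), n_subjects)),
      tibble::as_tibble(X)
    )
    tbl <- dplyr::left_join(tbl, truths, by = c("subject", "hand"))
    structure(tbl, channels = colnames(X), band = "gamma",
              class = c("hotspot_features", class(tbl)))
  })
}

# one cached quick subject simulation reused across tests (10 trials)
quick_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_subject(subject_spec(n_trials = 10, seed = 77))
    }
    cache
  }
})
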