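#' Study runners
#'
#' [run_band_study()] re-runs the full pipeline once per frequency band
#' (fixed channel set) and compares band-wise localization errors;
#' [run_channel_ablation()] re-runs it once per channel set (fixed band);
#' [run_erp_study()] characterizes the movement-related potential. All three
#' operate on a simulated (or loaded) cohort tibble with one recording per
#' subject/hand.
#'
#' @name studies
NULL

# band-power feature table assembled from a precomputed PSD array
.features_from_psd <- function(psd, info, band, channels, truths) {
  b <- .band_row(band)
  bp <- band_power(psd, b)
  colnames(bp) <- dimnames(psd)[[2]]
  X <- bp[, channels, drop = FALSE]
  out <- dplyr::bind_cols(info, tibble::as_tibble(X))
  out <- dplyr::left_join(out, tibble::as_tibble(truths)[, c("subject", "hand", "x", "y", "z")],
                          by = c("subject", "hand"))
  if (anyNA(out[c("x", "y", "z")])) abort("missing ground-truth hotspot for some trials")
  structure(out, band = b$band, channels = channels,
            class = c("hotspot_features", class(out)))
}

# preprocess every cohort recording once and cache trial spectra
.prepare_cohort <- function(cohort, artifacts = "none", window = c(-0.5, 0.5),
                            target_fs = 200, ...) {
  rows <- seq_len(nrow(cohort))
  purrr::map(rows, function(i) {
    ep <- preprocess_recording(cohort$recording[[i]], target_fs = target_fs,
                               artifacts = artifacts, window = window,
                               subject = cohort$subject[i], hand = cohort$hand[i],
                               ...)
    list(subject = cohort$subject[i], hand = cohort$hand[i],
         info = ep$info, psd = psd_epochs(ep))
  })
}

# run cross-validated localization for a set of (band, channel_set) conditions
.run_conditions <- function(cohort, conditions, montage, sets, n_folds, spec,
                            seed, artifacts, condition_col) {
  truths <- cohort_truths(cohort)
  prep <- .prepare_cohort(cohort, artifacts = artifacts)
  hands <- unique(cohort$hand)
  trial_errors <- purrr::map_dfr(seq_len(nrow(conditions)), function(ci) {
    band <- conditions$band[ci]
    set_name <- conditions$channel_set[ci]
    purrr::map_dfr(hands, function(h) {
      sub <- prep[vapply(prep, function(p) p$hand == h, logical(1))]
      set_def <- sets[[set_name]]
      hand_arg <- if (!is.null(set_def$per_hand)) h else "none"
      channels <- channel_set(montage, set_name, hand = hand_arg, sets = sets)
      info <- purrr::map_dfr(sub, "info")
      psd <- NULL
      for (p in sub) {
        psd <- if (is.null(psd)) p$psd else {
          out <- array(0, dim = c(dim(psd)[1] + dim(p$psd)[1], dim(psd)[2], dim(psd)[3]))
          out[seq_len(dim(psd)[1]), , ] <- psd
          out[dim(psd)[1] + seq_len(dim(p$psd)[1]), , ] <- p$psd
          structure(out, freqs = attr(p$psd, "freqs"), dimnames = dimnames(p$psd))
        }
      }
      ft <- .features_from_psd(psd, info, band, channels, truths)
      cv <- cross_validate(ft, n_folds = n_folds, spec = spec, seed = seed + ci)
      err <- prediction_errors(cv)
      err$band <- band
      err$channel_set <- set_name
      err
    })
  })
  subject_means <- trial_errors |>
    dplyr::group_by(.data$subject, .data$hand, .data$band, .data$channel_set) |>
    dplyr::summarise(mean_error_cm = mean(.data$error_cm), .groups = "drop")
  summary <- trial_errors |>
    error_summary(.data$hand, .data$band, .data$channel_set)

  anova <- NULL
  if (nrow(conditions) >= 2) {
    anova <- lapply(setNames(hands, hands), function(h) {
      sm <- subject_means[subject_means$hand == h, ]
      sm$condition <- sm[[condition_col]]
      rm_anova(sm, value = "mean_error_cm", condition = "condition")
    })
  }
  hand_tests <- NULL
  if (length(hands) == 2) {
    both <- subject_means |>
      dplyr::count(.data$subject) |>
      dplyr::filter(.data$n == 2 * nrow(conditions)) |>
      dplyr::pull(.data$subject)
    hand_tests <- purrr::map_dfr(seq_len(nrow(conditions)), function(ci) {
      sm <- subject_means[subject_means$band == conditions$band[ci] &
                            subject_means$channel_set == conditions$channel_set[ci] &
                            subject_means$subject %in% both, ]
      w <- tidyr::pivot_wider(sm[c("subject", "hand", "mean_error_cm")],
                              names_from = "hand", values_from = "mean_error_cm")
      tt <- paired_ttest(w[[hands[1]]], w[[hands[2]]])
      tibble::tibble(band = conditions$band[ci], channel_set = conditions$channel_set[ci],
                     a = hands[1], b = hands[2],
                     t = tt$t, df = tt$df, p = tt$p)
    })
  }
  structure(
    list(trial_errors = trial_errors, subject_means = subject_means,
         summary = summary, anova = anova, hand_tests = hand_tests,
         conditions = conditions, condition_col = condition_col),
    class = "hotspot_report"
  )
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat(sprintf("<hotspot_report> %d condition(s) x %d hand(s)\n",
              nrow(x$conditions), length(unique(x$summary$hand))))
  print(x$summary)
  if (!is.null(x$anova)) {
    for (h in names(x$anova)) {
      cat(sprintf("[%s] ", h)); print(x$anova[[h]])
    }
  }
  invisible(x)
}

#' Band comparison study
#'
#' Runs preprocessing, band-power feature extraction, and tenfold
#' cross-validated localization independently for each frequency band at a
#' fixed channel set, then compares bands with a repeated-measures ANOVA
#' (Bonferroni post-hocs) per hand and hands with paired t-tests per band.
#'
#' @param cohort A `hotspot_cohort` tibble (see [simulate_cohort()]).
#' @param bands Band names to analyze.
#' @param set_name Channel set used for every band.
#' @param montage Electrode montage.
#' @param sets Channel-set configuration.
#' @param n_folds Cross-validation folds.
#' @param spec [mlp_spec()] for the regressor.
#' @param seed Seed for fold plans.
#' @param artifacts Artifact-removal method for preprocessing.
#' @return A `hotspot_report`.
#' @export
run_band_study <- function(cohort, bands = eeg_bands()$band, set_name = "Ch_Set1",
                           montage = default_montage(),
                           sets = default_channel_sets(), n_folds = 10,
                           spec = mlp_spec(), seed = 1, artifacts = "none") {
  conditions <- tibble::tibble(band = bands, channel_set = set_name)
  .run_conditions(cohort, conditions, montage, sets, n_folds, spec, seed,
                  artifacts, condition_col = "band")
}

#' Channel-set ablation study
#'
#' Re-runs the pipeline per channel set at a fixed band (default gamma); the
#' network input layer is resized to the set's channel count each time.
#'
#' @inheritParams run_band_study
#' @param set_names Channel sets to compare.
#' @param band Band used for every set.
#' @return A `hotspot_report`.
#' @export
run_channel_ablation <- function(cohort, set_names = paste0("Ch_Set", 1:5),
                                 band = "gamma", montage = default_montage(),
                                 sets = default_channel_sets(), n_folds = 10,
                                 spec = mlp_spec(), seed = 1, artifacts = "none") {
  missing <- setdiff(set_names, names(sets))
  if (length(missing) > 0) {
    abort(paste0("undefined channel set(s): ", paste(missing, collapse = ", ")))
  }
  conditions <- tibble::tibble(band = band, channel_set = set_names)
  .run_conditions(cohort, conditions, montage, sets, n_folds, spec, seed,
                  artifacts, condition_col = "channel_set")
}

#' Movement-related potential study
#'
#' Epochs each recording at \eqn{[-1, 0.5)} s (baseline \eqn{[-1, -0.5)} s),
#' grand-averages the potential over the contralateral and ipsilateral
#' four-channel hemisphere groups, and detects peak amplitude/latency.
#'
#' @param cohort A `hotspot_cohort` tibble.
#' @param artifacts Artifact-removal method.
#' @param smooth_hz Zero-phase low-pass cutoff applied to the grand average
#'   before peak quantification (the returned waveform stays unfiltered);
#'   `NULL` disables. The movement-related negativity is a slow (< 8 Hz)
#'   deflection, so this suppresses residual broadband noise without biasing
#'   the peak.
#' @return List per hand with the `hotspot_erp` waveform tibble and detected
#'   `peaks`.
#' @export
run_erp_study <- function(cohort, artifacts = "none", smooth_hz = 12) {
  hands <- unique(cohort$hand)
  out <- lapply(setNames(hands, hands), function(h) {
    rows <- which(cohort$hand == h)
    eps <- lapply(rows, function(i) {
      preprocess_recording(cohort$recording[[i]], artifacts = artifacts,
                           window = c(-1, 0.5), subject = cohort$subject[i],
                           hand = cohort$hand[i])
    })
    # pool into one epoch set
    data <- do.call(abind_trials, lapply(eps, function(e) e$data))
    info <- purrr::map_dfr(eps, "info")
    pooled <- eeg_epochs(data, eps[[1]]$fs, eps[[1]]$window, eps[[1]]$labels, info)
    erp <- grand_average_erp(pooled, erp_group_channels(h))
    erp_det <- erp
    if (!is.null(smooth_hz)) {
      lp <- signal::butter(4, smooth_hz / (pooled$fs / 2), type = "low")
      erp_det <- erp |>
        dplyr::group_by(.data$group) |>
        dplyr::mutate(amplitude = signal::filtfilt(lp, .data$amplitude)) |>
        dplyr::ungroup()
      attributes(erp_det) <- c(attributes(erp_det),
                               attributes(erp)[c("fs", "baseline")])
      class(erp_det) <- class(erp)
    }
    list(erp = erp, peaks = detect_erp_peak(erp_det))
  })
  structure(out, class = "hotspot_erp_study")
}

# bind trial arrays along the first dimension
abind_trials <- function(...) {
  arrs <- list(...)
  dims <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(0, dim = c(n, dims[2], dims[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
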