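#' Euclidean error distance between predicted and true hotspots
#'
#' @param pred,truth Length-3 vectors or n x 3 matrices of coordinates (cm).
#' @return Distance(s) in cm.
#' @examples
#' euclidean_error(c(0, 0, 0), c(1, 2, 2))  # 3
#' @export
euclidean_error <- function(pred, truth) {
  if (is.null(dim(pred))) pred <- matrix(pred, ncol = 3)
  if (is.null(dim(truth))) truth <- matrix(truth, ncol = 3)
  d <- sqrt(rowSums((as.matrix(pred) - as.matrix(truth))^2))
  if (length(d) == 1) d[[1]] else d
}

#' Per-trial localization errors
#'
#' @param preds A `hotspot_predictions` tibble (truth `x/y/z` and
#'   `pred_x/pred_y/pred_z` columns).
#' @return The tibble with an `error_cm` column appended.
#' @export
prediction_errors <- function(preds) {
  tbl <- tibble::as_tibble(preds)
  if (anyNA(tbl[c("x", "y", "z")])) abort("missing ground-truth coordinates")
  tbl$error_cm <- euclidean_error(
    as.matrix(tbl[c("pred_x", "pred_y", "pred_z")]),
    as.matrix(tbl[c("x", "y", "z")])
  )
  tbl
}

#' Per-subject mean errors
#'
#' @param errors Tibble with `error_cm` (from [prediction_errors()]).
#' @param ... Grouping columns in addition to `subject` (e.g. `hand`, `band`).
#' @return Tibble of per-subject mean errors.
#' @export
subject_mean_errors <- function(errors, ...) {
  errors |>
    dplyr::group_by(.data$subject, ...) |>
    dplyr::summarise(mean_error_cm = mean(.data$error_cm), .groups = "drop")
}

#' Condition-level error summary
#'
#' Trial errors are first averaged within subject, then summarized across
#' subjects: grand mean, SD across subjects, and SE = SD / sqrt(n_subjects).
#'
#' @param errors Tibble with `subject` and `error_cm` columns.
#' @param ... Condition columns to summarize by (e.g. `band`, `channel_set`,
#'   `hand`).
#' @return Tibble with `mean_error_cm`, `sd_cm`, `se_cm`, `n_subjects`.
#' @export
error_summary <- function(errors, ...) {
  subject_mean_errors(errors, ...) |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      sd_cm = sd(.data$mean_error_cm),
      mean_error_cm = mean(.data$mean_error_cm),
      .groups = "drop"
    ) |>
    dplyr::mutate(se_cm = .data$sd_cm / sqrt(.data$n_subjects)) |>
    dplyr::relocate("mean_error_cm", "sd_cm", "se_cm", .after = "n_subjects")
}

#' One-way repeated-measures ANOVA with Bonferroni post-hocs
#'
#' Subjects are the blocking factor; conditions the within factor. The F test
#' comes from the standard within-subject decomposition
#' (`aov(value ~ condition + Error(subject/condition))`). Sphericity is
#' handled by the Greenhouse-Geisser estimate: the corrected p-value is
#' reported alongside and used for the omnibus verdict when epsilon < 0.75.
#' All pairwise conditions are compared by paired t-tests with Bonferroni
#' multiplication (capped at 1), and an ordering statement groups conditions
#' that are mutually indistinguishable, e.g. `"delta = theta > beta"`.
#'
#' @param data Tibble with one value per subject x condition.
#' @param value,subject,condition Column names (strings).
#' @param alpha Significance level for grouping in the ordering statement.
#' @return An object of class `rm_anova`: omnibus statistics, `pairwise`
#'   tibble, condition `means`, and `ordering` string.
#' @export
rm_anova <- function(data, value = "mean_error_cm", subject = "subject",
                     condition = "condition", alpha = 0.05) {
  d <- tibble::tibble(
    value = data[[value]],
    subject = factor(data[[subject]]),
    condition = factor(data[[condition]], levels = unique(data[[condition]]))
  )
  if (anyNA(d$value)) abort("missing cells in the subject x condition matrix")
  wide <- tidyr::pivot_wider(d, names_from = "condition", values_from = "value")
  M <- as.matrix(wide[, -1])
  if (anyNA(M)) abort("incomplete design: every subject needs every condition")
  n <- nrow(M); k <- ncol(M)
  if (k < 2 || n < 3) abort("need >= 2 conditions and >= 3 subjects")

  fit <- aov(value ~ condition + Error(subject / condition), data = d)
  tab <- summary(fit)[["Error: subject:condition"]][[1]]
  F_val <- tab["condition", "F value"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  p <- tab["condition", "Pr(>F)"]
  ss_cond <- tab["condition", "Sum Sq"]
  ss_scale <- sum((M - mean(M))^2) + 1e-300
  if (!is.finite(F_val) || ss_cond < 1e-12 * max(ss_scale, 1e-12)) {
    # no condition effect beyond floating-point dust: a null result
    F_val <- 0; p <- 1
  }
  # Greenhouse-Geisser epsilon from the double-centered covariance
  S <- stats::cov(M)
  Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- if (sum(Sc^2) < 1e-24) 1 else sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  eps <- min(1, max(1 / (k - 1), eps))
  p_gg <- pf(F_val, eps * df1, eps * df2, lower.tail = FALSE)

  conds <- colnames(M)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  m <- length(pairs)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    tt <- paired_ttest(M[, pr[1]], M[, pr[2]])
    tibble::tibble(a = pr[1], b = pr[2], t = tt$t, df = tt$df,
                   p_raw = tt$p, p_adj = min(1, m * tt$p))
  })
  means <- colMeans(M)

  structure(
    list(F = F_val, df1 = df1, df2 = df2, p = p,
         epsilon_gg = eps, p_gg = p_gg,
         p_used = if (eps < 0.75) p_gg else p,
         n_subjects = n, conditions = conds, means = means,
         pairwise = pairwise,
         ordering = .ordering_statement(means, pairwise, alpha)),
    class = "rm_anova"
  )
}

# group conditions into "=" clusters separated by ">" using pairwise verdicts
.ordering_statement <- function(means, pairwise, alpha = 0.05) {
  ord <- names(sort(means, decreasing = TRUE))
  sig <- function(a, b) {
    row <- pairwise[(pairwise$a == a & pairwise$b == b) |
                      (pairwise$a == b & pairwise$b == a), ]
    nrow(row) > 0 && row$p_adj[1] < alpha
  }
  groups <- list(ord[1])
  for (cn in ord[-1]) {
    cur <- groups[[length(groups)]]
    if (any(vapply(cur, sig, logical(1), b = cn))) {
      groups[[length(groups) + 1L]] <- cn
    } else {
      groups[[length(groups)]] <- c(cur, cn)
    }
  }
  paste(vapply(groups, paste, character(1), collapse = " = "), collapse = " > ")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%g, %g) = %.4g, p = %.4g (GG eps = %.3f, p_GG = %.4g)\n",
              x$df1, x$df2, x$F, x$p, x$epsilon_gg, x$p_gg))
  cat("ordering:", x$ordering, "\n")
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided paired t-test on per-subject values. Zero-variance differences
#' are handled explicitly: all-zero differences give t = 0, p = 1; constant
#' nonzero differences are flagged degenerate with p = 0.
#'
#' @param a,b Equal-length (>= 3) per-subject value vectors, paired by
#'   position.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) abort("paired samples must have equal length")
  if (length(a) < 3) abort("need at least 3 pairs")
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Grand-average movement-related potential
#'
#' Each trial is baseline-corrected by subtracting its mean over the baseline
#' window, averaged across trials within subject, across the group's four
#' channels, and finally across subjects.
#'
#' @param epochs An `eeg_epochs` object covering the baseline (window
#'   starting at -1.0 s); multi-subject epochs are averaged per subject first
#'   using the `subject` metadata column.
#' @param groups Named list of channel-label vectors (e.g. from
#'   [erp_group_channels()]).
#' @param baseline Baseline window in seconds, default `c(-1, -0.5)`.
#' @return Tibble of class `hotspot_erp`: `time`, `group`, `amplitude` (uV).
#' @export
grand_average_erp <- function(epochs, groups, baseline = c(-1, -0.5)) {
  times <- epoch_times(epochs)
  if (baseline[1] < epochs$window[1] - 1e-9) {
    abort(sprintf("epochs start at %g s but baseline needs %g s; re-epoch with an earlier window",
                  epochs$window[1], baseline[1]))
  }
  bidx <- which(times >= baseline[1] & times < baseline[2])
  missing <- setdiff(unlist(groups), epochs$labels)
  if (length(missing) > 0) {
    abort(paste0("group channel(s) not in epochs: ", paste(missing, collapse = ", ")))
  }
  dat <- epochs$data
  base <- apply(dat[, , bidx, drop = FALSE], c(1, 2), mean)
  dat <- sweep(dat, c(1, 2), base)
  subj <- as.character(epochs$info$subject)
  out <- purrr::map_dfr(names(groups), function(g) {
    ch_idx <- match(groups[[g]], epochs$labels)
    per_subj <- vapply(unique(subj), function(s) {
      tr <- which(subj == s)
      colMeans(matrix(apply(dat[tr, ch_idx, , drop = FALSE], 3, mean),
                      nrow = 1))  # mean over trials and group channels
    }, numeric(dim(dat)[3]))
    tibble::tibble(time = times, group = g, amplitude = rowMeans(per_subj))
  })
  structure(out, fs = epochs$fs, baseline = baseline,
            class = c("hotspot_erp", class(out)))
}

#' Detect the movement-related negativity peak
#'
#' The peak is the most negative sample inside the search window; its
#' amplitude (uV) and latency (ms relative to the press) are returned
#' together with the onset latency — the start of the sustained negative
#' deflection, defined as the first time the waveform drops below
#' `-onset_k` baseline standard deviations and stays there until the peak.
#' A flat waveform is flagged and gets an undefined latency.
#'
#' @param erp A `hotspot_erp` tibble (one group), or a numeric waveform with
#'   a `time` vector supplied.
#' @param time Sample times in seconds (if `erp` is a bare numeric vector).
#' @param search_window Window searched for the peak, s.
#' @param baseline Baseline window used for the onset threshold, s.
#' @param onset_k Onset threshold in baseline SDs.
#' @return Tibble: `amplitude_uv`, `latency_ms`, `onset_ms`, `flat`.
#' @export
detect_erp_peak <- function(erp, time = NULL, search_window = c(-0.5, 0.5),
                            baseline = c(-1, -0.5), onset_k = 2) {
  if (inherits(erp, "hotspot_erp") || is.data.frame(erp)) {
    if (length(unique(erp$group)) > 1) {
      return(purrr::map_dfr(split(erp, erp$group), function(g) {
        dplyr::bind_cols(tibble::tibble(group = g$group[1]),
                         detect_erp_peak(g$amplitude, g$time, search_window,
                                         baseline, onset_k))
      }))
    }
    time <- erp$time
    erp <- erp$amplitude
  }
  widx <- which(time >= search_window[1] & time <= search_window[2])
  if (length(widx) == 0) abort("search window outside the waveform")
  ipk <- widx[which.min(erp[widx])]
  amp <- erp[ipk]
  if (all(abs(erp[widx]) < 1e-12)) {
    return(tibble::tibble(amplitude_uv = 0, latency_ms = NA_real_,
                          onset_ms = NA_real_, flat = TRUE))
  }
  bidx <- which(time >= baseline[1] & time < baseline[2])
  thr <- -onset_k * max(sd(erp[bidx]), 1e-12)
  below <- erp <= thr
  onset <- NA_real_
  run_start <- NA_integer_
  for (i in seq_len(ipk)) {
    if (below[i] && is.na(run_start)) run_start <- i
    if (!below[i]) run_start <- NA_integer_
  }
  if (!is.na(run_start)) onset <- time[run_start] * 1000
  tibble::tibble(amplitude_uv = amp, latency_ms = time[ipk] * 1000,
                 onset_ms = onset, flat = FALSE)
}
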