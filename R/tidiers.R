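#' Broom-style tidiers
#'
#' `tidy()` returns the informative per-term/per-condition tibble of an
#' object; `glance()` a one-row model summary.
#'
#' @name tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn tidiers Pairwise Bonferroni-adjusted comparisons of an
#'   [rm_anova()] fit.
#' @param x Object to tidy.
#' @param ... Unused.
#' @export
tidy.rm_anova <- function(x, ...) x$pairwise

#' @describeIn tidiers One-row omnibus summary of an [rm_anova()] fit.
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$F, df1 = x$df1, df2 = x$df2, p.value = x$p,
                 epsilon_gg = x$epsilon_gg, p.value.gg = x$p_gg,
                 n_subjects = x$n_subjects, ordering = x$ordering)
}

#' @describeIn tidiers Condition-level error summary of a study report.
#' @export
tidy.hotspot_report <- function(x, ...) x$summary

#' @describeIn tidiers Omnibus test per hand for a study report.
#' @export
glance.hotspot_report <- function(x, ...) {
  if (is.null(x$anova)) return(tibble::tibble())
  purrr::map_dfr(names(x$anova), function(h) {
    dplyr::bind_cols(tibble::tibble(hand = h), glance(x$anova[[h]]))
  })
}

#' @describeIn tidiers Training history of a fitted network.
#' @export
tidy.hotspot_mlp <- function(x, ...) x$history

#' @describeIn tidiers One-row training summary of a fitted network.
#' @export
glance.hotspot_mlp <- function(x, ...) {
  tibble::tibble(n_inputs = length(x$scaler$mean), n_hidden = x$spec$n_hidden,
                 best_epoch = x$best_epoch, n_epochs = x$n_epochs,
                 best_loss = x$best_loss, monitor = x$monitor,
                 stopped_early = x$stopped_early)
}
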