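#' Plot methods
#'
#' `autoplot()` methods render the package's result types with ggplot2:
#' condition-wise mean error bars with SE whiskers for reports, and
#' baseline-shaded grand-average waveforms for movement-related potentials.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn plots Bar chart of condition mean errors with SE error bars.
#' @param object Result object.
#' @param ... Unused.
#' @export
autoplot.hotspot_report <- function(object, ...) {
  cond <- object$condition_col
  s <- object$summary
  s$condition <- factor(s[[cond]], levels = unique(object$conditions[[cond]]))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$condition, y = .data$mean_error_cm,
                                  fill = .data$hand)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_error_cm - .data$se_cm,
                   ymax = .data$mean_error_cm + .data$se_cm),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "mean error distance (cm)",
                  title = "Hotspot localization error",
                  subtitle = "subject-level means; error bars: standard error") +
    ggplot2::theme_minimal()
}

#' @describeIn plots Grand-average waveforms per hemisphere group with the
#'   baseline window shaded.
#' @export
autoplot.hotspot_erp <- function(object, ...) {
  baseline <- attr(object, "baseline")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time * 1000, y = .data$amplitude,
                                       color = .data$group)) +
    ggplot2::annotate("rect", xmin = baseline[1] * 1000, xmax = baseline[2] * 1000,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time relative to press (ms)", y = "amplitude (µV)",
                  title = "Grand-average movement-related potential",
                  subtitle = "negative up; shaded: baseline window") +
    ggplot2::theme_minimal()
}

#' Predicted vs true hotspot positions
#'
#' Projects 3D positions onto the axial (x-y) and coronal (x-z) planes;
#' predictions are drawn as points, ground truths as crosses.
#'
#' @param preds A `hotspot_predictions` tibble (optionally filtered).
#' @return A ggplot object faceted by projection plane.
#' @export
plot_hotspots <- function(preds) {
  tbl <- tibble::as_tibble(preds)
  long <- dplyr::bind_rows(
    tibble::tibble(plane = "axial (x-y)", h = tbl$pred_x, v = tbl$pred_y,
                   ht = tbl$x, vt = tbl$y, subject = tbl$subject),
    tibble::tibble(plane = "coronal (x-z)", h = tbl$pred_x, v = tbl$pred_z,
                   ht = tbl$x, vt = tbl$z, subject = tbl$subject)
  )
  ggplot2::ggplot(long, ggplot2::aes(color = .data$subject)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$h, y = .data$v), alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(ggplot2::aes(x = .data$ht, y = .data$vt), shape = 4,
                        size = 3, stroke = 1.2) +
    ggplot2::facet_wrap(~plane, scales = "free") +
    ggplot2::labs(x = "cm (Cz origin)", y = "cm",
                  title = "Predicted (dots) vs TMS-defined (crosses) hotspots") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
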