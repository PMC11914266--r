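#' Plot cohort Colocalization Factors
#'
#' Bar chart of the mean CF per region with SEM error bars, individual cells
#' overlaid as points, and the CF = 1 control level as a dashed line — the
#' conventional presentation of a per-cell colocalization analysis.
#'
#' @param object a [run_cohort()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cohort_result
#' @export
autoplot.cohort_result <- function(object, ...) {
  s <- object$summary
  d <- object$cells[object$cells$defined, ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$region, y = .data$mean_cf)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey30", width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_cf - .data$sem,
                   ymax = .data$mean_cf + .data$sem), width = 0.2) +
    ggplot2::geom_jitter(data = d,
                         ggplot2::aes(x = .data$region, y = .data$cf),
                         width = 0.12, size = 1.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Colocalization Factor",
                  subtitle = sprintf("%d cells; dashed line = control (CF = 1)",
                                     object$n_cells)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a Venn partition as exclusive-region percentages
#'
#' Bar chart of each exclusive membership pattern's percentage of the ROI —
#' the tabular equivalent of the per-cell Venn diagram.
#'
#' @param object a [partition_areas()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot venn_partition
#' @export
autoplot.venn_partition <- function(object, ...) {
  s <- venn_summary(object)
  s$region <- factor(s$region, levels = s$region)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$region, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = NULL, y = "% of ROI area") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Display a channel stack or its masks
#'
#' Raster view of each channel (and the ROI, if present) for quick visual
#' checks of simulated or loaded data.
#'
#' @param object a [channel_stack()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot channel_stack
#' @export
autoplot.channel_stack <- function(object, ...) {
  d <- bind_rows(imap(object$channels, function(plane, ch) {
    tibble(channel = ch,
           row = rep(seq_len(nrow(plane)), ncol(plane)),
           col = rep(seq_len(ncol(plane)), each = nrow(plane)),
           intensity = as.vector(plane))
  }))
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
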