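#' Manhattan-style plot of the windowed delta SNP index
#'
#' @param windows Output of [window_scan()].
#' @param threshold Optional genome-wide threshold (drawn at +/- the
#'   value).
#' @param regions Optional region tibble from [call_regions()], shaded.
#' @return A ggplot object.
#' @export
plot_delta_scan <- function(windows, threshold = NULL, regions = NULL) {
  dat <- windows %>%
    filter(!is.na(.data$mean_delta)) %>%
    mutate(mid = (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid / 1e6, y = .data$mean_delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70", linewidth = 0.3)
  if (!is.null(regions) && nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(
        xmin = .data$start / 1e6, xmax = .data$end / 1e6,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "gold", alpha = 0.25
    )
  }
  p <- p + ggplot2::geom_line(colour = "steelblue", linewidth = 0.4)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(
      yintercept = c(-threshold, threshold),
      linetype = "dashed", colour = "grey40"
    )
  }
  p +
    ggplot2::facet_grid(
      cols = ggplot2::vars(.data$chrom),
      scales = "free_x", space = "free_x"
    ) +
    ggplot2::labs(
      x = "position (Mb)", y = expression(Delta * " SNP index (window mean)")
    ) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(1, "pt"))
}

#' @method autoplot perm_null
#' @export
autoplot.perm_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$max_abs_delta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(
      xintercept = object$threshold, linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "genome-wide max |window mean delta| per iteration",
      y = "iterations",
      title = paste0(
        object$percentile, "th percentile threshold = ",
        signif(object$threshold, 3)
      )
    ) +
    ggplot2::theme_minimal(base_size = 10)
}

#' @method autoplot bsa_run
#' @export
autoplot.bsa_run <- function(object, ...) {
  plot_delta_scan(object$windows, object$threshold, object$regions)
}
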