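#' Quadrant plot of trigger versus cycle-off errors
#'
#' The graphical display of the interaction analysis: cycle-off error on the
#' x axis, trigger error on the y axis, both -100..100%, with the synchrony
#' box at +/- `sync_box_limit_pct`. Paired events are plotted at their error
#' coordinates; asynchronous events, which have no finite coordinates, are
#' annotated on the 100/100 periphery grouped by category with their counts.
#'
#' @param result A `neurosync` object.
#' @param config An [ns_config()] list (for the box limit).
#' @return A ggplot object.
#' @export
plot_quadrant <- function(result, config = result$config) {
  if (is.null(config)) config <- ns_config()
  box <- config$sync_box_limit_pct
  ev <- result$events
  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::annotate("rect", xmin = -box, xmax = box, ymin = -box,
                      ymax = box, fill = NA, colour = "black",
                      linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(-105, 105), ylim = c(-105, 105)) +
    ggplot2::labs(x = "cycle-off error (%)", y = "trigger error (%)") +
    ggplot2::theme_minimal()
  if (nrow(ev) == 0L) {
    return(p + ggplot2::annotate("text", x = 0, y = 0, label = "no events"))
  }
  finite <- ev[ev$category %in% c("paired", "multiple_assist_during_eadi"), ]
  if (nrow(finite)) {
    p <- p + ggplot2::geom_point(
      data = finite,
      ggplot2::aes(x = .data$cycleoff_error_pct, y = .data$trigger_error_pct,
                   shape = .data$category),
      colour = "steelblue", alpha = 0.7)
  }
  async <- result$category_counts
  async <- async[async$category %in% ASYNC_CATEGORIES & async$n > 0, ]
  if (nrow(async)) {
    lab <- tibble::tibble(
      x = 100, y = c(100, 88, 76)[seq_len(nrow(async))],
      txt = sprintf("%s: %d", async$category, async$n))
    p <- p + ggplot2::geom_text(
      data = lab, ggplot2::aes(x = .data$x, y = .data$y, label = .data$txt),
      hjust = 1, size = 3, colour = "firebrick")
  }
  p
}

#' @rdname plot_quadrant
#' @param object A `neurosync` object (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.neurosync <- function(object, ...) plot_quadrant(object)

#' Raw-tracing strip of EAdi and ventilator pressure
#'
#' @param record A `waveform_df` tibble.
#' @return A ggplot object with the two channels in stacked facets.
#' @export
plot_tracing <- function(record) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(unclass_waveform(record))[
      c("time_s", "eadi_uV", "paw_cmH2O")],
    cols = c("eadi_uV", "paw_cmH2O"),
    names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y",
                        strip.position = "left") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Event-distribution pie
#'
#' Relative distribution of interaction events: synchronous and
#' dyssynchronous paired events plus each asynchrony category.
#'
#' @param result A `neurosync` object.
#' @return A ggplot object.
#' @export
plot_event_pie <- function(result) {
  ev <- result$events
  slices <- if (nrow(ev)) {
    lab <- ifelse(ev$classification == "asynchrony", ev$category,
                  ev$classification)
    dplyr::count(tibble::tibble(label = lab), .data$label)
  } else {
    tibble::tibble(label = "no events", n = 1L)
  }
  slices$pct <- 100 * slices$n / sum(slices$n)
  ggplot2::ggplot(slices,
                  ggplot2::aes(x = "", y = .data$n, fill = .data$label)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.0f%%", .data$pct)),
      position = ggplot2::position_stack(vjust = 0.5), size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

hist_panel <- function(h, xlab) {
  if (nrow(h) == 0L) {
    return(ggplot2::ggplot() + ggplot2::labs(x = xlab, y = "n") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$n)) +
    ggplot2::geom_col(width = h$bin_hi[1] - h$bin_lo[1],
                      fill = "grey40") +
    ggplot2::labs(x = xlab, y = "n") +
    ggplot2::theme_minimal()
}

#' Dashboard composite display
#'
#' Bedside-style overview of one record: raw tracings, the event
#' distribution pie, the quadrant plot and breathing-pattern histograms
#' (ventilator and neural frequency, tidal volume, pressure above PEEP,
#' EAdi peaks). The tidal-volume panel is omitted (with a note) when the
#' record has no flow channel.
#'
#' @param result A `neurosync` object.
#' @param pattern A [breathing_pattern()] summary.
#' @param record The `waveform_df` the result came from.
#' @return A patchwork object (print or [save_plot()] it).
#' @export
plot_dashboard <- function(result, pattern, record) {
  left <- patchwork::wrap_plots(
    list(plot_tracing(record), plot_event_pie(result),
         plot_quadrant(result)), ncol = 1)
  panels <- list(
    hist_panel(pattern$histograms$f_v, "F_V (breaths/min)"),
    hist_panel(pattern$histograms$f_n, "F_N (breaths/min)"))
  if (any(is.finite(pattern$vt_L))) {
    panels <- c(panels, list(hist_panel(pattern$histograms$vt, "Vt (L)")))
  } else {
    message("no flow channel: tidal-volume panel omitted")
  }
  panels <- c(panels, list(
    hist_panel(pattern$histograms$pv, "P_V above PEEP (cmH2O)"),
    hist_panel(pattern$histograms$eadi, "EAdi peak (uV)")))
  right <- patchwork::wrap_plots(panels, ncol = 1)
  patchwork::wrap_plots(left, right, ncol = 2, widths = c(2, 1))
}

#' Save a plot to SVG or PNG
#'
#' @param plot A ggplot/patchwork object.
#' @param path Output path ending in `.svg` or `.png`.
#' @param width,height Device size in inches.
#' @param dpi Raster resolution for PNG.
#' @return `path`, invisibly.
#' @export
save_plot <- function(plot, path, width = 10, height = 7, dpi = 150) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("svg", "png")) {
    stop("unsupported output format: .", ext, " (use .svg or .png)",
         call. = FALSE)
  }
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
    print(plot)
    grDevices::dev.off()
  } else {
    ggplot2::ggsave(path, plot = plot, width = width, height = height,
                    dpi = dpi)
  }
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
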