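#' Plot the sliding-window delta-SNP-index scan
#'
#' Window means along each chromosome with the null threshold overlaid;
#' called regions, if supplied, are shaded.
#'
#' @param windows output of [sliding_windows()] /[attach_thresholds()].
#' @param calls optional output of [call_qtl()].
#' @param level which threshold to draw (0.95 or 0.99).
#' @return a ggplot object.
#' @export
plot_delta_snp <- function(windows, calls = NULL, level = 0.95) {
  qcol <- paste0("q", round(level * 100))
  mid <- (windows$start + windows$end) / 2
  d <- dplyr::mutate(tibble::as_tibble(windows), mid = mid)
  p <- ggplot2::ggplot(dplyr::filter(d, !.data$masked),
                       ggplot2::aes(x = .data$mid / 1e6, y = .data$mean_delta)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "mean |ΔSNP-index|") +
    ggplot2::theme_minimal()
  if (qcol %in% names(d)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data[[qcol]]),
                                colour = "firebrick", linetype = 2)
  }
  if (!is.null(calls) && nrow(calls)) {
    p <- p + ggplot2::geom_rect(
      data = calls, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      fill = "steelblue", alpha = 0.15)
  }
  p
}

#' Autoplot method for sliding-window scans
#'
#' @param object a `hopper_windows` tibble.
#' @param ... passed to [plot_delta_snp()].
#' @return a ggplot object.
#' @method autoplot hopper_windows
#' @export
autoplot.hopper_windows <- function(object, ...) plot_delta_snp(object, ...)

#' Histogram of line AUC values with pool membership
#'
#' @param auc_summary output of [average_auc()].
#' @param pools optional output of [select_extremes()].
#' @param binwidth histogram bin width in AUC units.
#' @return a ggplot object.
#' @export
plot_damage_distribution <- function(auc_summary, pools = NULL, binwidth = 1) {
  d <- tibble::as_tibble(auc_summary)
  d$pool <- "unselected"
  if (!is.null(pools)) {
    d$pool[match(pools$line, d$line)] <- pools$pool
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_auc, fill = .data$pool)) +
    ggplot2::geom_histogram(binwidth = binwidth, colour = "white") +
    ggplot2::scale_fill_manual(values = c(resistant = "forestgreen",
                                          susceptible = "firebrick",
                                          unselected = "grey70")) +
    ggplot2::labs(x = "mean damage AUC (score·days)", y = "lines") +
    ggplot2::theme_minimal()
}

#' Graphical genotype (introgression painting) plot
#'
#' @param segments output of [paint_introgression()].
#' @return a ggplot object with one row per line, segments coloured by
#'   origin.
#' @export
plot_introgression <- function(segments) {
  ggplot2::ggplot(tibble::as_tibble(segments),
                  ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                               ymin = as.numeric(factor(.data$line)) - 0.4,
                               ymax = as.numeric(factor(.data$line)) + 0.4,
                               fill = .data$origin)) +
    ggplot2::geom_rect() +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(factor(segments$line))),
      labels = levels(factor(segments$line))) +
    ggplot2::scale_fill_manual(values = c(donor = "firebrick",
                                          recipient = "grey80",
                                          heterozygous = "goldenrod",
                                          unknown = "white")) +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' D-prime heat triangle for a set of markers
#'
#' @param pairs output of [ld_matrix()].
#' @param marker_map data frame `marker`, `chrom`, `pos` used to order
#'   markers along the map.
#' @return a ggplot tile plot of pairwise D'.
#' @export
plot_ld_heatmap <- function(pairs, marker_map) {
  mm <- marker_map[order(marker_map$chrom, marker_map$pos), ]
  lev <- mm$marker
  d <- tibble::as_tibble(pairs) %>%
    dplyr::mutate(m1 = factor(.data$marker1, levels = lev),
                  m2 = factor(.data$marker2, levels = lev))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$m1, y = .data$m2,
                                  fill = .data$d_prime)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = "D'") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
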