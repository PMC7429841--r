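#' Plot a windowed recombination landscape
#'
#' Step plot of window rates (or counts) along each chromosome, optionally
#' highlighting hotspot calls.
#'
#' @param track A `window_track` tibble ([window_rates()] or
#'   [window_counts()]).
#' @param calls Optional `hotspot_calls` tibble to highlight.
#' @param value Column to plot (`"rate"` if present, else `"n"`).
#' @return A ggplot object.
#' @export
plot_landscape <- function(track, calls = NULL, value = NULL) {
  tr <- as_tibble(track)
  value <- value %||% if ("rate" %in% names(tr)) "rate" else "n"
  p <- ggplot2::ggplot(tr, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data[[value]]
  )) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "Position (Mb)",
      y = if (value == "rate") "Recombination rate" else "Crossover events"
    ) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(calls) && nrow(calls)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(calls),
      ggplot2::aes(
        xmin = .data$start / 1e6, xmax = .data$end / 1e6,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "red", alpha = 0.25
    )
  }
  p
}

#' Plot a pairwise recombination-fraction heat map
#'
#' The linkage heat map of one group: marker-by-marker recombination
#' fractions, low (tight linkage) dark, high (weak linkage) light.
#'
#' @param pairs Output of [pairwise_recfrac()].
#' @return A ggplot object.
#' @export
plot_recfrac_heatmap <- function(pairs) {
  pairs <- as_tibble(pairs)
  ids <- unique(c(pairs$marker1, pairs$marker2))
  full <- bind_rows(
    pairs,
    rename(pairs, marker1 = "marker2", marker2 = "marker1")
  ) %>% distinct(.data$marker1, .data$marker2, .keep_all = TRUE)
  ggplot2::ggplot(full, ggplot2::aes(
    x = factor(.data$marker1, ids), y = factor(.data$marker2, ids),
    fill = .data$recfrac
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "rec. fraction", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot parental-block haplotype maps
#'
#' One horizontal bar per sample and chromosome, coloured by parental
#' block state — the haplotype map used to eyeball crossover calls.
#'
#' @param blocks Output of [segment_blocks()].
#' @param chrom Optional single chromosome to show.
#' @return A ggplot object.
#' @export
plot_haplotypes <- function(blocks, chrom = NULL) {
  b <- as_tibble(blocks)
  if (!is.null(chrom)) b <- filter(b, .data$chrom == !!chrom)
  ggplot2::ggplot(b, ggplot2::aes(
    xmin = .data$start / 1e6, xmax = .data$end / 1e6,
    ymin = as.integer(factor(.data$sample)) - 0.4,
    ymax = as.integer(factor(.data$sample)) + 0.4,
    fill = .data$state
  )) +
    ggplot2::geom_rect() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(a = "#1b9e77", b = "#7570b3", h = "#d95f02")) +
    ggplot2::labs(x = "Position (Mb)", y = "Line") +
    ggplot2::theme_minimal(base_size = 9)
}

#' @rdname plot_landscape
#' @param object A `window_track`.
#' @param ... Passed to [plot_landscape()].
#' @importFrom ggplot2 autoplot
#' @export
autoplot.window_track <- function(object, ...) plot_landscape(object, ...)

#' @rdname plot_haplotypes
#' @param object A `geno_blocks` tibble.
#' @param ... Passed to [plot_haplotypes()].
#' @export
autoplot.geno_blocks <- function(object, ...) plot_haplotypes(object, ...)
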