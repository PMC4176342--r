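#' Plot a composite occupancy profile
#'
#' @param object A `composite_profile` from [composite_log2()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot composite_profile
#' @export
autoplot.composite_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mean_log2)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = sprintf("position relative to %s anchor (bp)",
                  attr(object, "anchor_kind") %||% "the"),
      y = expression(mean ~ log[2] ~ occupancy),
      title = sprintf("Composite profile (%d genes)", object$n_genes[1])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a two-condition comparison
#'
#' Overlays the two composite profiles and the per-position difference.
#'
#' @param object A `condition_comparison` from [compare_conditions()].
#' @param labels Length-2 condition labels.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot condition_comparison
#' @export
autoplot.condition_comparison <- function(object, labels = c("a", "b"), ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(object$composite_a, condition = labels[1]),
    dplyr::mutate(object$composite_b, condition = labels[2])
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$mean_log2,
                                  colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "position relative to anchor (bp)",
                  y = expression(mean ~ log[2] ~ occupancy)) +
    ggplot2::theme_minimal()
}

#' Plot coverage over a genomic window
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param from,to 0-based window bounds (half-open).
#' @param genes Optional gene models; TSS positions in the window are marked.
#' @return A ggplot.
#' @export
plot_coverage <- function(track, chrom, from, to, genes = NULL) {
  v <- track_slice(track, chrom, from, to)
  d <- tibble(pos = seq(from, length.out = length(v)), value = v)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom),
                  y = sprintf("occupancy (%s)", track$state)) +
    ggplot2::theme_minimal()
  if (!is.null(genes)) {
    tss <- genes$tss[genes$chrom == chrom & genes$tss >= from & genes$tss < to]
    if (length(tss) > 0) {
      p <- p + ggplot2::geom_vline(xintercept = tss, linetype = "dotted",
                                   colour = "steelblue")
    }
  }
  p
}
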