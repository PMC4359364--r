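# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Presence/absence matrix plot
#'
#' Tile view of a survey's per-species calls, the synthetic analogue of a
#' presence/absence figure: filled tiles for present, empty for absent,
#' grey for inconclusive.
#'
#' @param object A `cenh3_survey`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cenh3_survey <- function(object, ...) {
  df <- object$calls
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$species_id,
                                   fill = .data$status)) +
    ggplot2::geom_tile(colour = "grey30", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(
      present = "black", absent = "white", inconclusive = "grey70"
    )) +
    ggplot2::labs(x = NULL, y = NULL, fill = "call") +
    ggplot2::theme_minimal()
}

#' Coverage report plot
#'
#' Benchmark-proteome recovery fractions, one bar per assembly.
#'
#' @param object A `coverage_report` (one or more rows bound together).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_report <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$assembly_id, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "benchmark fraction recovered") +
    ggplot2::theme_minimal()
}

#' Abundance distribution plot
#'
#' Histogram of length-normalised abundances (log10) with optional
#' highlighted transcripts (e.g. the CenH3 transcript), mirroring the
#' abundance-profile view used as the expression-level control.
#'
#' @param object An `abundance_table` from [normalize_abundance()].
#' @param highlight Character vector of transcript ids to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abundance_table <- function(object, highlight = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$norm_abundance + 1e-3))) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::labs(x = "log10 normalised abundance", y = "transcripts") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    hi <- df[df$id %in% highlight, ]
    p <- p + ggplot2::geom_vline(
      data = hi,
      ggplot2::aes(xintercept = log10(.data$norm_abundance + 1e-3)),
      colour = "red"
    )
  }
  p
}

#' Plot a placement tree
#'
#' Draws the rooted tree behind a placement verdict with the candidate
#' highlighted (base-graphics, via ape).
#'
#' @param x A `placement_verdict` (or `histone_tree`).
#' @param ... Passed to [ape::plot.phylo()].
#' @return The input, invisibly.
#' @export
plot_placement <- function(x, ...) {
  phy <- if (inherits(x, "histone_tree")) x$tree else attr(x, "tree")
  cols <- rep("black", length(phy$tip.label))
  if (inherits(x, "placement_verdict")) {
    cols[phy$tip.label %in% x$candidate_id] <- "red"
  }
  ape::plot.phylo(phy, tip.color = cols, ...)
  invisible(x)
}
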