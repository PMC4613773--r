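# broom-style tidiers and plot helpers for the package's result objects.

#' Tidy a tiling path
#'
#' @param x A `tiling_path`.
#' @param ... Unused.
#' @return The contig tibble (one row per placed clone) with gap records
#'   appended as attributes left intact on `x`.
#' @export
tidy.tiling_path <- function(x, ...) x$contigs

#' One-row summary of a tiling path
#'
#' @param x A `tiling_path`.
#' @param ... Unused.
#' @return Tibble: clone, contig, gap, unplaced and conflict counts.
#' @export
glance.tiling_path <- function(x, ...) {
  tibble::tibble(n_clones = nrow(x$contigs) + length(x$unplaced),
                 n_contigs = length(unique(x$contigs$contig)),
                 n_gaps = nrow(x$gaps),
                 n_unplaced = length(x$unplaced),
                 n_conflicts = nrow(x$conflicts),
                 n_suspect_termini = nrow(x$suspect_termini))
}

#' Tidy a map comparison
#'
#' @param x A `map_comparison`.
#' @param ... Unused.
#' @return Long presence tibble (`locus_name`, `map`, `present`).
#' @export
tidy.map_comparison <- function(x, ...) {
  tidyr::pivot_longer(x$presence, -"locus_name",
                      names_to = "map", values_to = "present")
}

#' One-row-per-pair summary of a map comparison
#'
#' @param x A `map_comparison`.
#' @param ... Unused.
#' @return The pairwise concordance tibble with inverted-run counts.
#' @export
glance.map_comparison <- function(x, ...) {
  inv <- x$inverted_runs
  x$concordance %>%
    dplyr::rowwise() %>%
    dplyr::mutate(n_inverted_runs = if (nrow(inv)) sum(
      inv$map_a == .data$map_a & inv$map_b == .data$map_b) else 0L) %>%
    dplyr::ungroup()
}

#' Dotplot of word matches
#'
#' @param matches Tibble from [dotplot_matrix()].
#' @return A ggplot: forward matches ascending, reverse matches by native-b
#'   coordinate (anti-diagonals).
#' @export
plot_dotplot <- function(matches) {
  ggplot2::ggplot(matches, ggplot2::aes(x = .data$pos_a, y = .data$pos_b,
                                        colour = .data$orientation)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c(forward = "black", reverse = "red")) +
    ggplot2::labs(x = "position in a (bp)", y = "position in b (bp)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_dotplot
#' @param object A `tiling_path`.
#' @param ... Unused.
#' @export
autoplot.tiling_path <- function(object, ...) {
  d <- object$contigs
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$offset, xend = .data$offset + .data$length,
      y = .data$rank, yend = .data$rank, colour = .data$orientation),
      linewidth = 2) +
    ggplot2::geom_text(ggplot2::aes(x = .data$offset, y = .data$rank,
                                    label = .data$clone_id),
                       hjust = 0, vjust = -1, size = 2.5) +
    ggplot2::facet_wrap(~contig, scales = "free", ncol = 1) +
    ggplot2::labs(x = "contig coordinate (bp)", y = "clone rank") +
    ggplot2::theme_minimal()
}

#' @rdname plot_dotplot
#' @param comparison A `map_comparison`.
#' @export
plot_map_presence <- function(comparison) {
  tidy.map_comparison(comparison) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$map, y = .data$locus_name,
                                 fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "white")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
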