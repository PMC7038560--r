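#' Plot positional entropy profiles by class
#'
#' Line plot of the per-position trinucleotide entropy of positive and
#' negative samples; conserved positions (typically around the central
#' adenine of true 6mA windows) show as dips.
#'
#' @param samples Labeled sample tibble (`seq`, `label`).
#' @return A ggplot object.
#' @export
plot_entropy <- function(samples) {
  prof <- entropy_by_class(samples)
  ggplot2::ggplot(prof, ggplot2::aes(.data$position, .data$entropy,
                                     colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Trinucleotide start position", y = "Entropy (bits)",
                  colour = NULL) +
    ggplot2::ylim(0, 6)
}

#' Plot the top of an MRMD feature ranking
#'
#' @param ranking An [mrmd_rank()] result.
#' @param top Number of top features to show.
#' @return A ggplot object.
#' @export
plot_ranking <- function(ranking, top = 30L) {
  df <- utils::head(as_tibble(unclass(ranking)), top) |>
    tidyr::pivot_longer(c("relevance", "distance"), names_to = "component",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$feature, -.data$rank),
                                   .data$value, fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "MRMD score", fill = NULL)
}
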