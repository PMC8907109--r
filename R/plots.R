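## ggplot2 renderings of the result objects.  The fragment map follows the
## published convention: 5'-terminal fragments in blue, 3'-terminal in
## red, internal fragments as green bars; tracks with similarity above the
## `dark_cutoff` (default 0.9) are drawn at full opacity, weaker evidence
## lighter.

#' Plot a fragment map
#'
#' @param object A `fragment_map` from [build_fragment_map()].
#' @param dark_cutoff Similarity above which a track is drawn at full
#'   opacity.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fragment_map <- function(object, dark_cutoff = 0.9, ...) {
  tr <- object$tracks
  pos <- object$positions
  if (nrow(tr)) {
    tr <- dplyr::arrange(tr, .data$kind, .data$start, .data$end)
    tr$row <- seq_len(nrow(tr))
    tr$group <- factor(region_class(tr$kind),
                       levels = c("5'-end", "3'-end", "Middle"))
    tr$strong <- tr$similarity > dark_cutoff
  }
  p <- ggplot2::ggplot()
  if (nrow(tr))
    p <- p + ggplot2::geom_segment(
      data = tr,
      ggplot2::aes(x = .data$start - 0.45, xend = .data$end + 0.45,
                   y = .data$row, yend = .data$row,
                   colour = .data$group, alpha = .data$strong),
      linewidth = 2) +
      ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
                                  guide = "none") +
      ggplot2::scale_colour_manual(
        values = c(`5'-end` = "#3B6FB6", `3'-end` = "#C0392B",
                   Middle = "#27803B"),
        name = NULL, drop = FALSE)
  p + ggplot2::scale_x_continuous(breaks = pos$position,
                                  labels = pos$residue,
                                  limits = c(0.5, nrow(pos) + 0.5)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Fragment map: ", object$sequence)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' Plot region-class percentage abundances
#'
#' Bar chart of 5'-end / 3'-end / Middle percentage abundances for the
#' platinated and unplatinated evidence sets, as returned by
#' [classify_regions()].
#'
#' @param regions Tibble from [classify_regions()].
#' @return A ggplot object.
#' @export
plot_region_summary <- function(regions) {
  regions$class <- factor(regions$class,
                          levels = c("5'-end", "Middle", "3'-end"))
  ggplot2::ggplot(regions,
                  ggplot2::aes(x = .data$class, y = .data$percent,
                               fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of fragment ions", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a per-residue occurrence histogram
#'
#' @param hist Tibble from [residue_histogram()].
#' @return A ggplot object.
#' @export
plot_residue_histogram <- function(hist) {
  long <- tidyr::pivot_longer(hist, c("platinated", "unplatinated"),
                              names_to = "set", values_to = "count")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$position, y = .data$count,
                               fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = hist$position,
                                labels = hist$residue) +
    ggplot2::labs(x = NULL, y = "fragments covering residue", fill = NULL) +
    ggplot2::theme_minimal()
}
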