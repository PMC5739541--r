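# ggplot2 autoplot methods for the pipeline's result objects.

#' Plot a contact map as a histogram-equalized heatmap
#'
#' Applies [vc_normalize()] and [display_transform()] (unless `raw`),
#' mirroring the standard display convention for high-resolution Hi-C
#' heatmaps.
#'
#' @param object A [contact_map()].
#' @param n_gray_levels Display levels for histogram equalization.
#' @param raw Plot raw counts (log10) instead of the equalized transform.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_map <- function(object, n_gray_levels = 256, raw = FALSE, ...) {
  if (raw) {
    df <- tidy(object) %>%
      mutate(intensity = log10(.data$count + 1))
  } else {
    df <- as_tibble(display_transform(vc_normalize(object), n_gray_levels))
  }
  bs <- object$bin_size / 1e3
  df <- bind_rows(df, rename(df, bin1 = "bin2", bin2 = "bin1"))
  ggplot2::ggplot(df, ggplot2::aes(.data$bin1 * bs, .data$bin2 * bs,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick4") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("%s position (kb)", object$chrom),
                  y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a directionality track
#'
#' @param object A [directionality()] track.
#' @param ... Unused.
#' @return A ggplot of the weighted directionality score per bin.
#' @export
autoplot.directionality_track <- function(object, ...) {
  bs <- attr(object, "bin_size") / 1e3
  df <- filter(as_tibble(object), .data$defined)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin * bs, .data$weighted_score)) +
    ggplot2::geom_col(width = bs, fill = "steelblue4") +
    ggplot2::labs(x = sprintf("%s position (kb)", attr(object, "chrom")),
                  y = "weighted directionality") +
    ggplot2::theme_minimal()
}

#' Plot a metaplot (anchor) matrix as a heatmap
#'
#' Rows keep the matrix's sort order (boundary strength or four-way
#' category).
#'
#' @param object An [aggregate_signal()] matrix.
#' @param trans Value transform for display (`"identity"` or `"log1p"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.anchor_matrix <- function(object, trans = c("identity", "log1p"), ...) {
  trans <- match.arg(trans)
  df <- tidy(object)
  if (trans == "log1p") df$value <- log1p(df$value)
  ggplot2::ggplot(df, ggplot2::aes(.data$offset / 1e3, -.data$anchor,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy",
                                 na.value = "grey85") +
    ggplot2::labs(x = "offset from anchor (kb)", y = "anchors (sorted)",
                  fill = "signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot read-pair QC span histograms
#'
#' One panel per orientation class; a short-span hump confined to the
#' in-out panel is the signature of genomic contamination.
#'
#' @param object An [orientation_summary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pairs_qc <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$span_lo, y = .data$n)) +
    ggplot2::geom_step(color = "steelblue4") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~orientation) +
    ggplot2::labs(x = "pair span (bp)", y = "pairs") +
    ggplot2::theme_minimal()
}
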