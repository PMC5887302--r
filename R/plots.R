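#' Plotting
#'
#' ggplot2 renderings of the package's result types: overlaid zipfian
#' function plots (one curve per sample co-spectrum), 2D MDS embeddings
#' with optional highlighting of the latest batches, and hierarchically
#' ordered distance heatmaps.
#'
#' @name plots
NULL

#' Overlay zipfian co-spectrum function plots
#'
#' One curve per co-spectrum: x = ln(rank), y = self-information (nats).
#' Approximately linear curves indicate power-law word frequencies; the
#' slope tracks repeat content and sharp turning points flag technical
#' artefacts such as adapter read-through.
#'
#' @param zs A `zipfian_cospectrum` or a (named) list of them.
#' @param labels Optional grouping labels (one per co-spectrum) used for
#'   colour; defaults to the co-spectrum ids.
#' @param file Optional output path (PNG/SVG/PDF by extension); when given
#'   the plot is saved and the path returned invisibly.
#' @param width,height Device size in inches when saving.
#' @return A ggplot object, or (invisibly) `file` when saving.
#' @export
plot_zipfians <- function(zs, labels = NULL, file = NULL,
                          width = 7, height = 5) {
  if (inherits(zs, "zipfian_cospectrum")) zs <- list(zs)
  if (length(zs) == 0) stop_cospectra("empty-selection", "no co-spectra to plot")
  ids <- names(zs) %||% vapply(zs, function(z)
    attr(z, "model_id") %||% "z", character(1))
  ids <- make.unique(ids)
  labels <- labels %||% ids
  df <- bind_rows(lapply(seq_along(zs), function(i) {
    tibble(id = ids[i], label = labels[i],
           log_rank = log(zs[[i]]$rank), h = zs[[i]]$h)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$log_rank, .data$h,
                                        group = .data$id,
                                        colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "ln rank", y = "self-information (nats)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(labels)) > 12) p <- p + ggplot2::guides(colour = "none")
  if (!is.null(file)) {
    tryCatch(ggplot2::ggsave(file, p, width = width, height = height),
             error = function(e) stop_cospectra("write-failed", sprintf(
               "could not write '%s': %s", file, conditionMessage(e))))
    return(invisible(file))
  }
  p
}

#' @export
autoplot.zipfian_cospectrum <- function(object, ...) {
  plot_zipfians(list(object), ...)
}

#' @param object An `mds_embedding`.
#' @param highlight Optional character vector of item ids to overlay with
#'   text labels (e.g. the latest batches under review).
#' @param colour Optional vector (one per item) mapped to point colour.
#' @param ... Ignored.
#' @rdname mds_embed
#' @export
autoplot.mds_embedding <- function(object, highlight = NULL, colour = NULL,
                                   ...) {
  df <- as_tibble(object)
  df$colour <- colour %||% "item"
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                        colour = .data$colour)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = NULL) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p <- p + ggplot2::guides(colour = "none")
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_text(
      data = df[df$item %in% highlight, ],
      ggplot2::aes(label = .data$item),
      colour = "black", vjust = -0.8, size = 3)
  }
  p
}

#' @export
autoplot.dist_matrix <- function(object, ...) {
  ord <- heatmap_order(unclass(object))
  ids <- rownames(object)
  df <- tidy.dist_matrix(object)
  df2 <- tibble(item1 = df$item2, item2 = df$item1, distance = df$distance)
  diag_df <- tibble(item1 = ids, item2 = ids, distance = 0)
  df <- bind_rows(df, df2, diag_df)
  df$item1 <- factor(df$item1, levels = ids[ord$row_order])
  df$item2 <- factor(df$item2, levels = ids[ord$col_order])
  ggplot2::ggplot(df, ggplot2::aes(.data$item1, .data$item2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
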