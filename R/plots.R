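#' Plot a spanning tree on the scalp layout
#'
#' Draws the tree's edges between 2-D projected sensor positions; node
#' size maps the chosen metric and hubs are highlighted.
#'
#' @param object An `mst_tree`.
#' @param montage An `eeg_montage` whose labels match the tree.
#' @param criterion Hub criterion passed to [identify_hubs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mst_tree <- function(object, montage = load_montage(),
                              criterion = "bc", ...) {
  proj <- montage_projection_2d(montage)
  stopifnot(identical(object$labels, proj$label))
  nm <- node_metrics(object)
  hubs <- identify_hubs(nm, criterion = criterion)
  nodes <- dplyr::left_join(proj, nm, by = "label") |>
    dplyr::mutate(hub = .data$label %in% hubs$label)
  edges <- object$edges |>
    dplyr::mutate(x = proj$px[.data$from], y = proj$py[.data$from],
                  xend = proj$px[.data$to], yend = proj$py[.data$to])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      color = "grey50") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$px, y = .data$py,
                   size = .data[[criterion]], color = .data$hub)) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$px, y = .data$py, label = .data$label),
      vjust = -1, size = 2.6) +
    ggplot2::scale_linewidth(range = c(0.2, 1.4), guide = "none") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "steelblue",
                                           `TRUE` = "firebrick")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(color = "hub", size = criterion)
}

#' Plot per-channel group statistics on the scalp layout
#'
#' @param object An `eegmst_clusters` result.
#' @param montage The `eeg_montage` used for the test.
#' @param ... Unused.
#' @return A ggplot object showing channel-wise z statistics with
#'   significant-cluster members outlined.
#' @export
autoplot.eegmst_clusters <- function(object, montage = load_montage(), ...) {
  proj <- montage_projection_2d(montage)
  z <- attr(object, "z")
  sig_channels <- unlist(object$channels[object$significant %||% logical(0)])
  df <- dplyr::mutate(proj, z = z,
                      in_cluster = .data$label %in% sig_channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$z,
                                     color = .data$in_cluster),
                        shape = 21, size = 6, stroke = 1.1) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -1.4, size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "navy", high = "darkred",
                                  mid = "white") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey70",
                                           `TRUE` = "black"),
                                guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "rank-sum z")
}

#' Plot global measure comparisons across bands
#'
#' One panel per measure, p-values per band with the corrected threshold.
#'
#' @param tests A tibble of comparison results (e.g.
#'   `run$global_tests`).
#' @return A ggplot object.
#' @export
plot_global_tests <- function(tests) {
  stopifnot(all(c("measure", "band", "p_value") %in% names(tests)))
  ggplot2::ggplot(tests,
                  ggplot2::aes(x = .data$band, y = .data$p_value,
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$corrected_alpha),
                        linetype = 2) +
    ggplot2::facet_wrap(~ .data$measure) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "permutation p-value") +
    ggplot2::theme_minimal()
}
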