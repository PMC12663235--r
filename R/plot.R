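# ggplot2 helpers for inspecting scenes, probability maps and benchmark
# results.

raster_df <- function(mat, value = "value") {
  df <- tibble(
    row = rep(seq_len(nrow(mat)), times = ncol(mat)),
    col = rep(seq_len(ncol(mat)), each = nrow(mat))
  )
  df[[value]] <- as.vector(mat)
  df
}

#' Plot a synthetic scene
#'
#' Shows the rendered image with the ground-truth, detector and segmenter
#' mask outlines overlaid as facets.
#'
#' @param scene a `synthetic_scene`.
#' @return a ggplot object.
#' @export
plot_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  img <- scene$image
  df <- raster_df(img[, , 1], "r")
  df$g <- as.vector(img[, , 2]); df$b <- as.vector(img[, , 3])
  df$fill <- grDevices::rgb(df$r, df$g, df$b, maxColorValue = 255)
  masks <- dplyr::bind_rows(
    dplyr::mutate(raster_df(scene$gt_semantic, "on"), layer = "ground truth"),
    dplyr::mutate(raster_df(scene$mask_d, "on"), layer = "mask_d"),
    dplyr::mutate(raster_df(scene$mask_s, "on"), layer = "mask_s")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_tile(
      data = dplyr::filter(masks, .data$on == 1),
      fill = NA, color = "black", linewidth = 0.1
    ) +
    ggplot2::facet_wrap(~layer) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a foreground probability map
#'
#' @param object a `probability_map`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot probability_map
#' @export
autoplot.probability_map <- function(object, ...) {
  df <- raster_df(object$p, "p")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "P(foreground)") +
    ggplot2::theme_minimal()
}

#' Plot benchmark results
#'
#' Per-seed Dice of the two candidate masks and the reconciled mask, as
#' returned by [run_benchmark()].
#'
#' @param bench tibble from [run_benchmark()].
#' @return a ggplot object.
#' @export
plot_benchmark <- function(bench) {
  long <- tidyr::pivot_longer(
    bench, c("dice_d", "dice_s", "dice_reconciled"),
    names_to = "mask", values_to = "dice"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$seed, y = .data$dice,
                                     color = .data$mask)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "scene seed", y = "Dice vs ground truth") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
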