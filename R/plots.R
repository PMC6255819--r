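#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_tile
#'   scale_fill_gradient scale_fill_viridis_c scale_y_log10 labs theme_minimal
#'   coord_fixed
#' @export
ggplot2::autoplot

#' Plot a phantom image (and its ROI outline) as a raster
#'
#' @param object A `phantom`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom <- function(object, ...) {
  df <- tidy_raster(object$image)
  p <- ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    coord_fixed() +
    labs(title = sprintf("%s phantom (seed %d)", object$class_label,
                         object$seed),
         x = NULL, y = NULL, fill = "intensity") +
    theme_minimal()
  if (any(object$roi_mask > 0)) {
    mdf <- tidy_raster(object$roi_mask)
    p <- p + geom_tile(data = mdf[mdf$value > 0, ],
                       fill = NA, colour = "red", linewidth = 0.1)
  }
  p
}

tidy_raster <- function(m) {
  tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                 col = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.vector(m))
}

#' Plot a synthesis loss trajectory
#'
#' @param object A `synthesis_result`.
#' @param ... Unused.
#' @return A ggplot object (log-scale loss vs iteration).
#' @export
autoplot.synthesis_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$iteration, y = .data$loss)) +
    geom_line() +
    scale_y_log10() +
    labs(title = "Gram-matching loss", x = "iteration", y = "loss") +
    theme_minimal()
}

#' Plot an RDM as a heatmap
#'
#' @param object An `rdm` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdm <- function(object, ...) {
  df <- tidy(object)
  df$condition_a <- factor(df$condition_a, levels = rownames(object))
  df$condition_b <- factor(df$condition_b, levels = rownames(object))
  ggplot(df, aes(x = .data$condition_b, y = .data$condition_a,
                 fill = .data$dissimilarity)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 100), direction = -1) +
    coord_fixed() +
    labs(title = "Representational dissimilarity matrix",
         x = NULL, y = NULL, fill = "dissimilarity") +
    theme_minimal()
}

#' @export
plot.phantom <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.synthesis_result <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.rdm <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.linkage_tree <- function(x, ...) plot(x$hclust, ...)
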