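#' Overlay label boundaries on an RGB image
#'
#' Draws each fibre's outline (pixels adjacent to a different label or to
#' background) in green over the input image — the usual visual check of a
#' segmentation against the histology.
#'
#' @param img an [rgb_image].
#' @param labels a [label_mask] of the same shape.
#' @param colour outline colour as an RGB triple in `[0, 1]`.
#' @return An [rgb_image].
#' @export
label_overlay <- function(img, labels, colour = c(0, 0.8, 0.2)) {
  lab <- as_plain(labels)
  edge <- matrix(FALSE, nrow(lab), ncol(lab))
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    sh <- shift_mat(lab, d[1], d[2])
    edge <- edge | (lab != sh & (lab > 0L | sh > 0L))
  }
  px <- as_plain_rgb(img)
  for (k in 1:3) {
    plane <- px[, , k]
    plane[edge] <- colour[k]
    px[, , k] <- plane
  }
  rgb_image(px, px_scale_um = px_scale(img))
}

#' Plot an image or mask with ggplot2
#'
#' @param x an [rgb_image], [gray_image] or [label_mask].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_image <- function(x, ...) {
  if (inherits(x, "rgb_image")) {
    px <- as_plain_rgb(x)
    cols <- grDevices::rgb(px[, , 1], px[, , 2], px[, , 3])
  } else if (inherits(x, "label_mask")) {
    lab <- as_plain(x)
    pal <- c("#222222", grDevices::hcl.colors(max(max(lab), 1L), "Spectral"))
    cols <- pal[lab + 1L]
  } else {
    g <- as_plain(x)
    cols <- grDevices::gray(pmin(pmax(g, 0), 1))
  }
  H <- nrow(x); W <- ncol(x)
  df <- data.frame(x = rep(seq_len(W), each = H),
                   y = rep(rev(seq_len(H)), W),
                   fill = as.vector(cols))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
}

#' @rdname cdf_estimate
#' @param object a `cdf_estimate`.
#' @param ... unused.
#' @method autoplot cdf_estimate
#' @export
autoplot.cdf_estimate <- function(object, ...) {
  df <- data.frame(misclassification = object$grid, cdf = object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$misclassification, .data$cdf)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::labs(x = "misclassification (%)",
                  y = "cumulative probability",
                  title = sprintf("Misclassification CDF (bandwidth %.2f)",
                                  object$bandwidth)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname evaluate_segmentation
#' @param object a `metrics_report`.
#' @param ... unused.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- data.frame(diameter = object$diameters_um)
  ggplot2::ggplot(df, ggplot2::aes(.data$diameter)) +
    ggplot2::geom_histogram(bins = 20, fill = "#b2182b", colour = "white") +
    ggplot2::labs(x = "minor-axis diameter (um)", y = "fibres",
                  title = sprintf("Fibre diameters (mean %.1f um, VC %.1f)",
                                  object$mean_diameter_um, object$vc)) +
    ggplot2::theme_minimal()
}

#' @rdname evaluate_batch
#' @param object a `metrics_batch`.
#' @param ... unused.
#' @method autoplot metrics_batch
#' @export
autoplot.metrics_batch <- function(object, ...) {
  df <- as.data.frame(tidy(object))
  long <- data.frame(
    image = rep(df$image, 3),
    metric = rep(c("accuracy", "fragmentation", "congealment"),
                 each = nrow(df)),
    value = c(df$accuracy, df$fragmentation, df$congealment)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$image, .data$value)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
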