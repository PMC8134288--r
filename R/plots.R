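# ggplot2 visualizations for images, training histories and error maps.

raster_df <- function(m) {
  data.frame(row = as.vector(row(m)), col = as.vector(col(m)),
             value = as.vector(m))
}

#' Plot a B-mode frame (or any image matrix)
#'
#' @param x A `usgan_bmode`, or a matrix of 8-bit intensities.
#' @param title Optional title.
#' @return A ggplot object (grayscale raster, probe at the top).
#' @export
plot_bmode <- function(x, title = NULL) {
  m <- if (inherits(x, "usgan_bmode")) x$values else x
  df <- raster_df(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Loss curves of a training run
#'
#' @param object A `usgan_gan`.
#' @param ... Unused.
#' @return ggplot of discriminator/adversarial/L1 losses against step,
#'   with held-out masked L1 overlaid.
#' @export
autoplot.usgan_gan <- function(object, ...) {
  h <- object$history
  long <- rbind(
    data.frame(step = h$step, loss = h$loss_d, term = "discriminator"),
    data.frame(step = h$step, loss = h$loss_g_adv, term = "generator (adv)"),
    data.frame(step = h$step, loss = h$loss_g_l1, term = "generator (L1)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$loss,
                                     colour = .data$term)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(data = data.frame(step = object$validation$step,
                                          loss = object$validation$val_l1,
                                          term = "held-out masked L1"),
                        size = 1.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step", y = "loss", colour = NULL,
                  title = sprintf("%s training", object$variant)) +
    ggplot2::theme_minimal()
}

#' Spatial patch chi-squared error map
#'
#' @param object A `usgan_pchi2` (from [pchi2()]).
#' @param ... Unused.
#' @return ggplot raster of per-patch values, fixed to the `[0, 1]` scale.
#' @export
autoplot.usgan_pchi2 <- function(object, ...) {
  df <- raster_df(object$map)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                  name = expression(chi^2)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("patch chi-squared (RMS %.3f)", object$value),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Paired-difference box plot of an ablation run
#'
#' @param object A `usgan_ablation`.
#' @param baseline Baseline variant for paired differences.
#' @param ... Unused.
#' @return ggplot of per-image metric differences against the baseline.
#' @export
autoplot.usgan_ablation <- function(object, baseline = "SA2H", ...) {
  pd <- paired_differences(object$per_image, baseline)
  if (nrow(pd) == 0) {
    # nothing to pair against: show absolute per-image metrics instead
    p <- object$per_image
    long <- rbind(
      data.frame(variant = p$variant, metric = "psnr", value = p$psnr),
      data.frame(variant = p$variant, metric = "mae", value = p$mae),
      data.frame(variant = p$variant, metric = "pchi2", value = p$pchi2))
    return(ggplot2::ggplot(long, ggplot2::aes(x = .data$variant,
                                              y = .data$value)) +
             ggplot2::geom_boxplot() +
             ggplot2::facet_wrap(~metric, scales = "free_y") +
             ggplot2::labs(x = NULL, y = "per-image value") +
             ggplot2::theme_minimal())
  }
  n <- nrow(pd)
  long <- rbind(
    data.frame(variant = pd$variant, metric = rep("d_psnr", n), value = pd$d_psnr),
    data.frame(variant = pd$variant, metric = rep("d_mae", n), value = pd$d_mae),
    data.frame(variant = pd$variant, metric = rep("d_pchi2", n), value = pd$d_pchi2))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variant, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = sprintf("difference vs %s", baseline)) +
    ggplot2::theme_minimal()
}

#' Write a spatial error map as a PNG with a [0, 1] colormap
#'
#' @param map A `usgan_pchi2` or a matrix of values in `[0, 1]`.
#' @param path PNG path.
#' @param upscale Integer pixel replication factor for visibility.
#' @export
write_pchi2_png <- function(map, path, upscale = 8L) {
  m <- if (inherits(map, "usgan_pchi2")) map$map else map
  m <- pmin(pmax(m, 0), 1)
  pal <- grDevices::hcl.colors(256, "viridis")
  idx <- matrix(pmin(floor(m * 255) + 1, 256), nrow(m), ncol(m))
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  big <- array(0, c(nrow(m) * upscale, ncol(m) * upscale, 3))
  for (k in 1:3) {
    ch <- matrix(rgb[k, ], nrow(m), ncol(m))
    big[, , k] <- ch[rep(seq_len(nrow(m)), each = upscale),
                     rep(seq_len(ncol(m)), each = upscale)]
  }
  png::writePNG(big, path)
  invisible(path)
}
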