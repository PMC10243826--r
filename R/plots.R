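#' Plot a synthetic field: hub mask, HIEL centers, puncta
#'
#' @param object An `en_face_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot en_face_field
#' @export
autoplot.en_face_field <- function(object, ...) {
  px <- object$spec$px_size_um
  idx <- which(object$hub, arr.ind = TRUE)
  hub_df <- tibble(x = px_center_x(idx[, 2], px),
                   y = px_center_y(idx[, 1], px))
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = hub_df,
                         ggplot2::aes(x = .data$x, y = .data$y),
                         fill = "grey70") +
    ggplot2::geom_point(data = object$hiel,
                        ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                     size = .data$diameter_um),
                        shape = 21, stroke = 0.3) +
    ggplot2::scale_size_continuous(range = c(0.5, 2.5)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", size = "HIEL Ø (µm)",
                  title = paste0(object$spec$placement_mode, " vs ",
                                 object$spec$hub_kind)) +
    ggplot2::theme_minimal()
  if (nrow(object$puncta) > 0)
    p <- p + ggplot2::geom_point(
      data = object$puncta,
      ggplot2::aes(x = .data$x_um, y = .data$y_um,
                   color = .data$marker), size = 0.8)
  p
}

#' Plot one channel of a field frame as an intensity raster
#'
#' @param frame A [field_frame()].
#' @param channel Channel name (default first).
#' @return A ggplot object.
#' @export
plot_channel <- function(frame, channel = names(frame$channels)[1]) {
  img <- frame$channels[[channel]]
  px <- frame$px_size_um
  df <- tibble(
    x = rep(px_center_x(seq_len(ncol(img)), px), each = nrow(img)),
    y = rep(px_center_y(seq_len(nrow(img)), px), times = ncol(img)),
    intensity = as.vector(img))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", title = channel) +
    ggplot2::theme_minimal()
}
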