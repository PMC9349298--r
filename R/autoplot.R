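#' @export
autoplot.herd_mesh <- function(object, ...) {
  Tr <- object$triangles
  V <- object$vertices
  df <- tibble(
    tri = rep(seq_len(nrow(Tr)), each = 3L),
    lon = as.vector(t(matrix(V[t(Tr), 1], nrow(Tr), 3L, byrow = TRUE))),
    lat = as.vector(t(matrix(V[t(Tr), 2], nrow(Tr), 3L, byrow = TRUE))),
    inner = rep(object$inner, each = 3L))
  bnd <- as_tibble(as.data.frame(object$boundary))
  names(bnd) <- c("lon", "lat")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   group = .data$tri)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = .data$inner),
                          colour = "grey40", linewidth = 0.15, alpha = 0.4) +
    ggplot2::geom_polygon(data = cbind(bnd, tri = 0), colour = "red",
                          fill = NA, linewidth = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c("white", "steelblue")) +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "inner")
}

#' @export
autoplot.herd_fit <- function(object, ...) {
  ch <- object$chain
  ch$iteration <- seq_len(nrow(ch))
  long <- tidyr::pivot_longer(ch, -"iteration",
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "kept iteration", y = "hyperparameter value")
}

#' @export
autoplot.herd_smoothed <- function(object, centers = NULL, ...) {
  if (is.null(centers)) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$county_id, y = .data$median)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$median - .data$se, 0),
                                            ymax = .data$median + .data$se)) +
      ggplot2::labs(x = "county", y = "smoothed density (livestock per human)")
  } else {
    df <- dplyr::left_join(as_tibble(object),
                           dplyr::rename(as_tibble(centers),
                                         county_id = dplyr::any_of(c("area_id", "county_id"))),
                           by = "county_id")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                     fill = .data$median)) +
      ggplot2::geom_tile() +
      ggplot2::coord_equal() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "longitude", y = "latitude", fill = "density")
  }
}
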