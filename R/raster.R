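#' Tidy raster grids
#'
#' Rasters are represented as tibbles of cell centers (`lon`, `lat`, one
#' column per layer) carrying the grid geometry in attributes: origin
#' (lower-left corner of the lower-left cell), resolution, and dimensions.
#' Cells follow a half-open convention anchored at the bounding-box corner:
#' cell (i, j) covers `[x0 + (i-1) res, x0 + i res)`.
#'
#' @param bbox named vector `xmin, ymin, xmax, ymax` (or a boundary polygon).
#' @param resolution cell size in degrees.
#' @return tibble with `ix`, `iy`, `lon`, `lat` and attributes `origin`,
#'   `resolution`, `ncol`, `nrow`; class `herd_raster`.
#' @export
raster_grid <- function(bbox, resolution) {
  if (is.matrix(bbox)) bbox <- bbox_of(bbox)
  nc <- ceiling((bbox["xmax"] - bbox["xmin"]) / resolution - 1e-9)
  nr <- ceiling((bbox["ymax"] - bbox["ymin"]) / resolution - 1e-9)
  g <- tidyr::expand_grid(iy = seq_len(nr), ix = seq_len(nc))
  g <- tibble(ix = g$ix, iy = g$iy,
              lon = unname(bbox["xmin"]) + (g$ix - 0.5) * resolution,
              lat = unname(bbox["ymin"]) + (g$iy - 0.5) * resolution)
  structure(g, origin = unname(c(bbox["xmin"], bbox["ymin"])),
            resolution = resolution, ncol = as.integer(nc),
            nrow = as.integer(nr),
            class = c("herd_raster", class(g)))
}

raster_meta <- function(r) {
  list(origin = attr(r, "origin"), resolution = attr(r, "resolution"),
       ncol = attr(r, "ncol"), nrow = attr(r, "nrow"))
}

#' Look up raster layer values at arbitrary points (nearest cell)
#' @param r a `herd_raster`.
#' @param lon,lat point coordinates.
#' @param layer layer (column) name.
#' @return numeric vector; NA outside the grid.
#' @export
raster_lookup <- function(r, lon, lat, layer) {
  m <- raster_meta(r)
  ix <- floor((lon - m$origin[1]) / m$resolution) + 1L
  iy <- floor((lat - m$origin[2]) / m$resolution) + 1L
  key <- (r$iy - 1L) * m$ncol + r$ix
  idx <- match((iy - 1L) * m$ncol + ix, key)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(idx) & ix >= 1 & ix <= m$ncol & iy >= 1 & iy <= m$nrow
  out[ok] <- r[[layer]][idx[ok]]
  out
}

#' Write / read one raster layer as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south), readable
#' by standard GIS tools. Values are written with full double precision so a
#' write/read round trip is exact to within print precision.
#'
#' @param r a `herd_raster` (may be cropped; missing cells become nodata).
#' @param layer layer name to write.
#' @param path output path (conventionally `.asc`).
#' @param nodata sentinel for cells without data.
#' @export
write_raster_asc <- function(r, layer, path, nodata = -9999) {
  m <- raster_meta(r)
  vals <- matrix(nodata, m$nrow, m$ncol)
  vals[cbind(r$iy, r$ix)] <- ifelse(is.na(r[[layer]]), nodata, r[[layer]])
  hdr <- c(paste("ncols", m$ncol), paste("nrows", m$nrow),
           paste("xllcorner", format(m$origin[1], digits = 15)),
           paste("yllcorner", format(m$origin[2], digits = 15)),
           paste("cellsize", format(m$resolution, digits = 15)),
           paste("NODATA_value", nodata))
  rows <- vapply(seq(m$nrow, 1L), function(iy)
    paste(format(vals[iy, ], digits = 17, trim = TRUE, scientific = TRUE),
          collapse = " "), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_raster_asc
#' @export
read_raster_asc <- function(path, layer = "value") {
  ln <- readLines(path)
  hdr <- strsplit(trimws(ln[1:6]), "\\s+")
  hv <- setNames(vapply(hdr, function(h) as.numeric(h[2]), numeric(1)),
                 vapply(hdr, function(h) tolower(h[1]), character(1)))
  nc <- as.integer(hv["ncols"]); nr <- as.integer(hv["nrows"])
  vals <- matrix(scan(text = paste(ln[-(1:6)], collapse = "\n"), quiet = TRUE),
                 nrow = nr, ncol = nc, byrow = TRUE)
  vals <- vals[seq(nr, 1L), , drop = FALSE]  # back to south-to-north
  g <- raster_grid(c(xmin = hv[["xllcorner"]], ymin = hv[["yllcorner"]],
                     xmax = hv[["xllcorner"]] + nc * hv[["cellsize"]],
                     ymax = hv[["yllcorner"]] + nr * hv[["cellsize"]]),
                   hv[["cellsize"]])
  v <- vals[cbind(g$iy, g$ix)]
  v[v == hv[["nodata_value"]]] <- NA_real_
  g[[layer]] <- v
  g
}

#' @export
autoplot.herd_raster <- function(object, layer = NULL, ...) {
  if (is.null(layer))
    layer <- setdiff(names(object), c("ix", "iy", "lon", "lat"))[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       fill = .data[[layer]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = layer)
}
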