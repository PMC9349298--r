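#' Polygon utilities on planar lon/lat coordinates
#'
#' All geometry in the package treats longitude/latitude degrees as planar
#' Euclidean coordinates (the study regions are near the equator and all
#' model scales are specified in degrees).
#'
#' @param poly numeric matrix with two columns (lon, lat); the ring need not
#'   be explicitly closed.
#' @return `polygon_area()` returns the unsigned area (square degrees).
#' @keywords internal
#' @name geometry
NULL

as_ring <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L) abort("polygon must have two columns (lon, lat)")
  storage.mode(poly) <- "double"
  n <- nrow(poly)
  if (n >= 2L && all(poly[1L, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3L) abort("polygon must have at least 3 distinct vertices")
  poly
}

#' @rdname geometry
polygon_area <- function(poly) {
  p <- as_ring(poly)
  x <- p[, 1L]; y <- p[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

segments_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2); d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' @rdname geometry
polygon_is_simple <- function(poly) {
  p <- as_ring(poly)
  n <- nrow(p)
  idx <- rbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(p[idx[1L, i], ], p[idx[2L, i], ],
                             p[idx[1L, j], ], p[idx[2L, j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

check_boundary <- function(poly) {
  p <- as_ring(poly)
  if (polygon_area(p) <= 0) abort("degenerate polygon: zero area")
  if (!polygon_is_simple(p)) abort("geometry error: polygon is self-intersecting")
  p
}

#' Test whether points fall inside a polygon
#'
#' Even-odd ray casting; points exactly on an edge count as inside.
#'
#' @param lon,lat numeric vectors of point coordinates.
#' @param poly two-column matrix of polygon vertices.
#' @return logical vector.
#' @export
point_in_polygon <- function(lon, lat, poly) {
  p <- as_ring(poly)
  px <- p[, 1L]; py <- p[, 2L]
  nxt <- c(seq_len(nrow(p))[-1L], 1L)
  inside <- logical(length(lon))
  for (e in seq_len(nrow(p))) {
    x1 <- px[e]; y1 <- py[e]; x2 <- px[nxt[e]]; y2 <- py[nxt[e]]
    crosses <- ((y1 > lat) != (y2 > lat))
    if (any(crosses)) {
      xint <- x1 + (lat[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- lon[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
  }
  inside
}

bbox_of <- function(poly) {
  p <- as_ring(poly)
  c(xmin = min(p[, 1L]), ymin = min(p[, 2L]), xmax = max(p[, 1L]), ymax = max(p[, 2L]))
}

#' Square boundary helper
#'
#' Convenience constructor for the synthetic-country boundary used throughout
#' examples and tests.
#'
#' @param xmin,ymin lower-left corner in degrees.
#' @param width,height extent in degrees.
#' @return two-column matrix of vertices (counter-clockwise).
#' @export
square_boundary <- function(xmin = 0, ymin = 0, width = 2, height = width) {
  cbind(lon = c(xmin, xmin + width, xmin + width, xmin),
        lat = c(ymin, ymin, ymin + height, ymin + height))
}

#' Read and write polygon boundaries as GeoJSON
#'
#' Minimal GeoJSON support for a single Polygon (or the first Polygon of a
#' FeatureCollection). JSON parsing is delegated to jsonlite.
#'
#' @param path file path.
#' @param poly two-column matrix of vertices.
#' @export
read_boundary_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- g
  if (!is.null(g$type) && g$type == "FeatureCollection") geom <- g$features$geometry
  if (!is.null(geom$type)) {
    type <- geom$type[[1]]
    coords <- geom$coordinates
    if (is.list(coords)) coords <- coords[[1]]
    if (length(dim(coords)) == 3L) coords <- coords[1L, , ]
    if (!identical(type, "Polygon")) abort("expected a GeoJSON Polygon")
    return(as_ring(coords))
  }
  abort("unrecognized GeoJSON structure")
}

#' @rdname read_boundary_geojson
#' @export
write_boundary_geojson <- function(poly, path) {
  p <- as_ring(poly)
  ring <- rbind(p, p[1L, , drop = FALSE])
  obj <- list(type = "Polygon",
              coordinates = list(lapply(seq_len(nrow(ring)), function(i) ring[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Partition a boundary's bounding box into a grid of rectangular areas
#'
#' Used to generate synthetic districts (survey strata) and counties. Each
#' area is a bbox cell; only cells whose center lies inside the polygon (or
#' that contain sampled points) are meaningful, but ids cover the full grid
#' so lookups are O(1).
#'
#' @param boundary polygon matrix.
#' @param nx,ny number of cells in each direction.
#' @return a list with `assign(lon, lat)` mapping points to area ids and
#'   `adjacency` (rook neighbourhood) among the nx*ny cells, plus cell-center
#'   coordinates.
#' @export
grid_partition <- function(boundary, nx = 4L, ny = 4L) {
  bb <- bbox_of(boundary)
  w <- (bb["xmax"] - bb["xmin"]) / nx
  h <- (bb["ymax"] - bb["ymin"]) / ny
  assign_fun <- function(lon, lat) {
    ix <- pmin(pmax(floor((lon - bb["xmin"]) / w), 0), nx - 1)
    iy <- pmin(pmax(floor((lat - bb["ymin"]) / h), 0), ny - 1)
    as.integer(iy * nx + ix + 1L)
  }
  n <- nx * ny
  ii <- integer(0); jj <- integer(0)
  for (iy in 0:(ny - 1L)) for (ix in 0:(nx - 1L)) {
    id <- iy * nx + ix + 1L
    if (ix < nx - 1L) { ii <- c(ii, id); jj <- c(jj, id + 1L) }
    if (iy < ny - 1L) { ii <- c(ii, id); jj <- c(jj, id + nx) }
  }
  adj <- sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1, dims = c(n, n))
  centers <- tibble(
    area_id = seq_len(n),
    lon = bb["xmin"] + (((seq_len(n) - 1L) %% nx) + 0.5) * w,
    lat = bb["ymin"] + (((seq_len(n) - 1L) %/% nx) + 0.5) * h
  )
  list(nx = nx, ny = ny, bbox = bb, assign = assign_fun, adjacency = adj,
       centers = centers)
}

#' Uniform points inside a polygon by rejection sampling
#' @keywords internal
runif_in_polygon <- function(n, poly) {
  bb <- bbox_of(poly)
  lon <- numeric(0); lat <- numeric(0)
  while (length(lon) < n) {
    m <- max(2L * (n - length(lon)), 16L)
    x <- runif(m, bb["xmin"], bb["xmax"])
    y <- runif(m, bb["ymin"], bb["ymax"])
    keep <- point_in_polygon(x, y, poly)
    lon <- c(lon, x[keep]); lat <- c(lat, y[keep])
  }
  cbind(lon = lon[seq_len(n)], lat = lat[seq_len(n)])
}
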