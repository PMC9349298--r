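#' Regular prediction grid over a boundary
#'
#' Lays a lattice of square cells (default 0.017 degrees, about 2 km at the
#' equator) over the boundary's bounding box, keeps cells whose center falls
#' inside the polygon, and attaches per-cell covariate values sampled at
#' cell centers from the covariate rasters. No cells are masked as
#' unsuitable: water, urban and protected cells are retained and flagged so
#' downstream users can make their own calls.
#'
#' @param boundary polygon matrix.
#' @param resolution cell size in degrees (default 0.017).
#' @param covariates a `herd_raster` with the model covariate layers
#'   (optional; required to predict with covariate models).
#' @return tibble of class `herd_grid` (a `herd_raster` cropped to the
#'   boundary) with covariate columns and `flag_water`/`flag_urban`/
#'   `flag_protected` metadata columns where those layers exist.
#' @export
make_grid <- function(boundary, resolution = 0.017, covariates = NULL) {
  poly <- check_boundary(boundary)
  g <- raster_grid(poly, resolution)
  keep <- point_in_polygon(g$lon, g$lat, poly)
  meta <- raster_meta(g)
  g <- g[keep, ]
  if (!is.null(covariates)) {
    for (layer in setdiff(names(covariates), c("ix", "iy", "lon", "lat"))) {
      g[[layer]] <- raster_lookup(covariates, g$lon, g$lat, layer)
      if (anyNA(g[[layer]])) {
        bad <- which(is.na(g[[layer]]))
        abort(paste0("covariate '", layer, "' does not cover ", length(bad),
                     " grid cell(s), e.g. cell ", bad[1]))
      }
    }
    for (fl in intersect(c("water", "urban", "protected"), names(g)))
      g[[paste0("flag_", fl)]] <- g[[fl]] == 1
  }
  structure(g, origin = meta$origin, resolution = meta$resolution,
            ncol = meta$ncol, nrow = meta$nrow,
            class = c("herd_grid", "herd_raster", class(tibble())))
}

#' Predict the livestock-per-human density surface
#'
#' Evaluates, per posterior draw and grid cell,
#' `exp(alpha0 + x'beta + S(s) + omega_t + u(s, t))` -- the linear predictor
#' without iid effects and without the human-count offset, so the result is
#' livestock per one human ("flattened" population). Cell summaries are the
#' posterior median and the width of the central 95% interval across draws.
#'
#' @param draws a `herd_draws` from [posterior_sample()] (prediction mode,
#'   i.e. without iid effects).
#' @param grid a `herd_grid` from [make_grid()].
#' @param year prediction year; must lie within the fitted span.
#' @param ci_level credible level for the width band (default 0.95).
#' @return tibble of class `herd_density` with columns `lon`, `lat`,
#'   `median`, `ci_width`; attributes `year`, `species`, `resolution`.
#' @export
predict_density <- function(draws, grid, year, ci_level = 0.95) {
  stopifnot(inherits(draws, "herd_draws"))
  if (!year %in% draws$years)
    abort(paste0("year ", year, " outside the fitted span (",
                 min(draws$years), "-", max(draws$years),
                 "); no extrapolation beyond the configured window"))
  if (any(draws$blocks$block %in% c("eps", "gamma", "eta")))
    abort("draws include iid effects; use posterior_sample(include_iid = FALSE)")
  spec <- draws$spec
  t_i <- match(year, draws$years)
  ncell <- nrow(grid)

  fx <- draws_block(draws, "fixed")
  Xg <- matrix(1, ncell, 1L)
  covs <- setdiff(spec$fixed_effects, "intercept")
  for (v in covs) {
    if (!v %in% names(grid)) abort(paste0("grid lacks covariate '", v, "'"))
    col <- as.numeric(grid[[v]])
    if (v %in% names(draws$scaling)) {
      sc <- draws$scaling[[v]]
      col <- (col - sc["center"]) / sc["scale"]
    }
    Xg <- cbind(Xg, col)
  }
  eta <- tcrossprod(fx, Xg)  # n_draws x ncell

  if (isTRUE(spec$effects$spde) || isTRUE(spec$effects$spacetime))
    Ag <- project_points(draws$mesh, cbind(grid$lon, grid$lat))
  if (isTRUE(spec$effects$spde))
    eta <- eta + tcrossprod(draws_block(draws, "spde"), Ag)
  if (isTRUE(spec$effects$rw))
    eta <- eta + draws_block(draws, "rw")[, t_i]
  if (isTRUE(spec$effects$spacetime)) {
    st <- draws_block(draws, "st")
    cols <- ((t_i - 1L) * draws$nv + 1L):(t_i * draws$nv)
    eta <- eta + tcrossprod(st[, cols, drop = FALSE], Ag)
  }
  dens <- exp(eta)
  ql <- (1 - ci_level) / 2
  med <- apply(dens, 2L, median)
  lo <- apply(dens, 2L, quantile, probs = ql)
  hi <- apply(dens, 2L, quantile, probs = 1 - ql)
  out <- tibble(ix = grid$ix, iy = grid$iy, lon = grid$lon, lat = grid$lat,
                median = med, ci_width = hi - lo)
  meta <- raster_meta(grid)
  structure(out, year = year, species = spec$species,
            origin = meta$origin, resolution = meta$resolution,
            ncol = meta$ncol, nrow = meta$nrow, ci_level = ci_level,
            class = c("herd_density", "herd_raster", class(tibble())))
}

#' Write density surfaces to georeferenced plain-text rasters
#'
#' One ESRI ASCII grid per band, named `<species>_<year>_<band>.asc`;
#' cells outside the boundary carry the nodata sentinel.
#'
#' @param raster a `herd_density`.
#' @param dir output directory (created if needed).
#' @param nodata sentinel value.
#' @return invisible character vector of the written paths.
#' @export
write_density_raster <- function(raster, dir, nodata = -9999) {
  stopifnot(inherits(raster, "herd_density"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- attr(raster, "species"); yr <- attr(raster, "year")
  paths <- character(0)
  for (band in c("median", "ci_width")) {
    p <- file.path(dir, paste0(sp, "_", yr, "_", band, ".asc"))
    write_raster_asc(raster, band, p, nodata = nodata)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
autoplot.herd_density <- function(object, band = c("median", "ci_width"), ...) {
  band <- match.arg(band)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       fill = .data[[band]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::labs(
      x = "longitude", y = "latitude", fill = band,
      title = paste0(attr(object, "species"), " density, ", attr(object, "year")),
      subtitle = if (band == "median") "posterior median (livestock per human)"
                 else "width of the posterior 95% credible interval")
}
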