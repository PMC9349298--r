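#' Read and validate a cluster-level survey table
#'
#' Expected CSV schema: `cluster_id`, `survey_id`, `year`, `lon`, `lat`,
#' `district`, `urban`, `human_count`, plus count columns. Counts may be a
#' single `cattle_count` / `pig_count` column, or category columns
#' (`cattle_local`, `cattle_exotic`, `cattle_dairy`, ...) which are summed
#' at read time. Optional covariates (`protected`, `water`, `elevation`)
#' are carried through.
#'
#' Filtering rules: a year given as a range ("2010-2011") is resolved to
#' its first year; clusters missing the requested species' count are
#' dropped from that species' dataset only; clusters missing both species
#' are removed outright and counted in the attached log.
#'
#' @param path CSV path.
#' @param species `"cattle"` or `"pig"`.
#' @return cluster tibble with `livestock_count` set to the requested
#'   species; `attr(, "filter_log")` records the row accounting.
#' @export
read_cluster_table <- function(path, species = c("cattle", "pig")) {
  species <- match.arg(species)
  if (!file.exists(path)) abort(paste0("input path does not exist: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cluster_id", "survey_id", "year", "lon", "lat", "district",
            "urban", "human_count")
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort(paste0("cluster table violates schema; missing columns: ",
                 paste(miss, collapse = ", ")))
  # survey years spanning two calendar years resolve to the first year
  d$year <- as.integer(sub("^([0-9]{4}).*$", "\\1", as.character(d$year)))
  if (anyNA(d$year)) abort("unparseable year values")
  for (sp in c("cattle", "pig")) {
    cn <- paste0(sp, "_count")
    if (!cn %in% names(d)) {
      cats <- grep(paste0("^", sp, "_"), names(d), value = TRUE)
      cats <- setdiff(cats, cn)
      if (length(cats))
        d[[cn]] <- rowSums(d[, cats, drop = FALSE])
    }
  }
  if (!any(c("cattle_count", "pig_count") %in% names(d)))
    abort("cluster table has no livestock count columns")
  if (!"cattle_count" %in% names(d)) d$cattle_count <- NA_real_
  if (!"pig_count" %in% names(d)) d$pig_count <- NA_real_
  both_missing <- is.na(d$cattle_count) & is.na(d$pig_count)
  kept <- d[!both_missing, ]
  target <- paste0(species, "_count")
  sp_missing <- is.na(kept[[target]])
  out <- kept[!sp_missing, ]
  out$livestock_count <- as.integer(out[[target]])
  out$species <- species
  if (any(out$human_count < 1)) abort("human_count must be >= 1 in every row")
  attr(out, "filter_log") <- tibble(
    n_input = nrow(d), n_dropped_both_missing = sum(both_missing),
    n_dropped_species_missing = sum(sp_missing), n_used = nrow(out),
    species = species)
  out
}

#' Read and validate a household census table
#'
#' Schema: `household_id`, `county_id`, `weight`, `livestock_count`,
#' `household_size`.
#' @param path CSV path.
#' @export
read_household_table <- function(path) {
  if (!file.exists(path)) abort(paste0("input path does not exist: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("household_id", "county_id", "weight", "livestock_count",
            "household_size")
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort(paste0("household table violates schema; missing columns: ",
                 paste(miss, collapse = ", ")))
  if (any(d$weight <= 0)) abort("weights must be > 0")
  if (any(d$household_size < 1)) abort("household_size must be >= 1")
  if (any(d$livestock_count < 0)) abort("livestock_count must be >= 0")
  d
}

#' Run configuration
#'
#' A single structured list, serializable to YAML, holding everything a
#' pipeline run needs. Every stochastic stage has an explicit seed derived
#' from the master seed; a configuration without a seed refuses to run.
#'
#' @param seed master seed (mandatory).
#' @param species species to model.
#' @param model model menu id (1-6) or `"drc_restricted"`.
#' @param years survey years.
#' @param resolution prediction resolution in degrees.
#' @param outdir output directory.
#' @param sim named list of overrides for [synthetic_config()].
#' @param fit named list of overrides for [fit_control()].
#' @param ... further fields kept verbatim.
#' @export
run_config <- function(seed, species = "cattle", model = 2,
                       years = 2006:2010, resolution = 0.05,
                       outdir = "herdmaps-output", sim = list(),
                       fit = list(), ...) {
  if (missing(seed) || is.null(seed)) abort("a run without a seed refuses to start")
  cfg <- list(seed = as.integer(seed), species = species, model = model,
              years = as.integer(years), resolution = resolution,
              outdir = outdir, sim = sim, fit = fit, ...)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "herd_run_config")
}

#' @rdname run_config
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$hash <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$hash <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

log_line <- function(logfile, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  inform(msg)
}

#' Run the full synthetic pipeline
#'
#' simulate -> urbanicity -> fit -> predict (-> cv) -> sae, writing CSV
#' tables, plain-text rasters, the smoothed county estimates, and a
#' structured log. Re-running with the same config reproduces identical
#' outputs.
#'
#' @param config a `herd_run_config`.
#' @param run_cv run the six-model cross-validation (slow; default FALSE).
#' @return invisible list of artifact paths.
#' @export
run_pipeline <- function(config, run_cv = FALSE) {
  stopifnot(inherits(config, "herd_run_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  cat("", file = logfile)
  log_line(logfile, "run config hash ", config$hash, ", seed ", config$seed)

  sim_cfg <- do.call(synthetic_config,
                     modifyList(list(seed = config$seed, years = config$years,
                                     species = config$species),
                                config$sim))
  covs <- simulate_covariates(sim_cfg)
  mesh <- do.call(build_mesh, c(list(sim_cfg$boundary), sim_cfg$mesh_args))
  log_line(logfile, "mesh: ", nrow(mesh$vertices), " vertices, settings ",
           mesh$inner_max_edge, "/", mesh$outer_max_edge, "/", mesh$extension)
  clusters <- simulate_survey(sim_cfg, covs, mesh)
  cl_path <- file.path(outdir, "clusters.csv")
  write_records_csv(clusters, cl_path)
  log_line(logfile, "simulated ", nrow(clusters), " clusters; zero fraction ",
           round(mean(clusters$livestock_count == 0, na.rm = TRUE), 3))

  urb_data <- tibble(urban = clusters$urban,
                     popdensity = raster_lookup(covs, clusters$lon, clusters$lat, "popdensity"),
                     nightlights = raster_lookup(covs, clusters$lon, clusters$lat, "nightlights"))
  urb_paths <- character(0)
  if (length(unique(urb_data$urban)) > 1L) {
    um <- fit_urban(urb_data, split_seed = config$seed + 11L)
    surf <- predict_urban_surface(um, covs)
    up <- file.path(outdir, "urban_surface.asc")
    write_raster_asc(surf, "urban_pred", up)
    urb_paths <- up
    log_line(logfile, "urbanicity accuracies: ",
             paste(um$accuracy$class, round(um$accuracy$accuracy, 3),
                   collapse = ", "))
  } else log_line(logfile, "urbanicity skipped: single class")

  spec <- if (identical(config$model, "drc_restricted"))
    model_spec("drc_restricted", species = config$species)
  else model_spec(config$model, species = config$species)
  ctrl <- do.call(fit_control,
                  modifyList(list(seed = config$seed + 23L), config$fit))
  usable <- clusters[!is.na(clusters$livestock_count), ]
  fit <- fit_zip_model(usable, mesh, spec, default_priors(), ctrl)
  log_line(logfile, "fit: model ", spec$model, ", priors logged as ",
           "rho_s PC(", default_priors()$matern$rho0, ",",
           default_priors()$matern$alpha_rho, "), method ", ctrl$method)

  draws <- posterior_sample(fit, n = 500L, seed = config$seed + 31L)
  grid <- make_grid(sim_cfg$boundary, config$resolution, covs)
  ras_paths <- character(0)
  for (yr in range(config$years)) {
    dr <- predict_density(draws, grid, yr)
    ras_paths <- c(ras_paths, write_density_raster(dr, outdir))
  }
  log_line(logfile, "predicted ", length(ras_paths), " raster bands")

  cv_path <- NULL
  if (run_cv) {
    folds <- make_folds(usable, seed = config$seed + 41L)
    cvres <- cv_model_menu(usable, mesh, folds, restricted = TRUE,
                           species = config$species,
                           control = fit_control(method = "map",
                                                 seed = config$seed + 43L))
    cv_path <- file.path(outdir, "cv_report.csv")
    readr::write_csv(cvres, cv_path)
    sel <- select_model(cvres)
    log_line(logfile, "cv selected model ", sel$model_id)
  }

  census <- simulate_census(sim_cfg)
  hh_path <- file.path(outdir, "households.csv")
  write_records_csv(census, hh_path)
  counties <- attr(census, "counties")
  est <- area_estimates(census, n_counties = nrow(counties$centers))
  sm <- smooth_areas(est, counties$adjacency, seed = config$seed + 53L)
  sae_paths <- write_area_estimates(
    sm, counties$centers,
    file.path(outdir, "sae_estimates.csv"),
    file.path(outdir, "sae_estimates.geojson"))
  log_line(logfile, "sae: ", nrow(sm), " counties smoothed")

  invisible(list(clusters = cl_path, households = hh_path,
                 rasters = ras_paths, urban = urb_paths, cv = cv_path,
                 sae = sae_paths, log = logfile))
}
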