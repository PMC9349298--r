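#' Configuration for the synthetic-data generator
#'
#' The generator draws a synthetic country (covariate rasters), multi-year
#' cluster surveys from the zero-inflated Poisson model with known
#' hyperparameters, and a weighted household census, standing in for the
#' access-restricted survey microdata the method was designed for. All
#' latent draws are recorded alongside the data so parameter-recovery tests
#' can compare posteriors against the truth.
#'
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @param boundary polygon matrix (lon/lat degrees); default 2x2 degree square.
#' @param years integer vector of contiguous survey years.
#' @param n_surveys number of surveys (assigned to years round-robin).
#' @param clusters_per_survey clusters sampled per survey.
#' @param households_per_cluster sampled households per cluster (drives the
#'   human-count offset).
#' @param mean_household_size mean persons per household; the within-cluster
#'   household count distribution is not fixed by the survey sources, so it
#'   is exposed here.
#' @param resolution covariate raster resolution (degrees).
#' @param urban_fraction,protected_fraction,water_fraction target fractions
#'   of cells for the binary rasters; `urban_fraction = 0` produces an
#'   all-rural country.
#' @param n_districts_x,n_districts_y survey strata as a grid partition of
#'   the bounding box.
#' @param temporal_order order of the generating temporal random walk.
#' @param missing_rate completely-at-random missingness rate applied to the
#'   livestock counts.
#' @param species species label attached to the records.
#' @param true_params named list overriding any of the generative
#'   hyperparameters: `alpha0`, `beta` (named vector over urban, protected,
#'   water, elevation), `sigma_s`, `rho_s` (degrees), `sigma_rw`,
#'   `sigma_iid`, `sigma_survey`, `sigma_year`, `sigma_st`, `rho_t`,
#'   `p_zero`.
#' @param mesh_args list passed to [build_mesh()].
#' @return validated list of class `herd_sim_config`.
#' @export
synthetic_config <- function(seed,
                             boundary = square_boundary(0, 0, 2, 2),
                             years = 2006:2010,
                             n_surveys = 5L,
                             clusters_per_survey = 160L,
                             households_per_cluster = 25L,
                             mean_household_size = 4.5,
                             resolution = 0.05,
                             urban_fraction = 0.15,
                             protected_fraction = 0.1,
                             water_fraction = 0.05,
                             n_districts_x = 4L, n_districts_y = 4L,
                             temporal_order = 2L,
                             missing_rate = 0,
                             species = c("cattle", "pig"),
                             true_params = list(),
                             mesh_args = list(inner_max_edge = 0.25,
                                              outer_max_edge = 0.6,
                                              extension = 1)) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  species <- match.arg(species)
  boundary <- check_boundary(boundary)
  years <- as.integer(years)
  if (length(years) > 1 && !all(diff(sort(years)) == 1L))
    abort("years must be contiguous")
  tp <- modifyList(list(
    alpha0 = -2,
    beta = c(urban = 0.5, protected = -0.3, water = -0.2, elevation = 0.3),
    sigma_s = 0.5, rho_s = 0.5,
    sigma_rw = 0.2, sigma_iid = 0.3, sigma_survey = 0.2, sigma_year = 0.1,
    sigma_st = 0.2, rho_t = 0.7, p_zero = 0.1), true_params)
  sds <- c(tp$sigma_s, tp$sigma_rw, tp$sigma_iid, tp$sigma_survey,
           tp$sigma_year, tp$sigma_st)
  if (any(sds < 0) || tp$rho_s <= 0) abort("variance parameters must be >= 0 and rho_s > 0")
  if (abs(tp$rho_t) >= 1) abort("rho_t must lie in (-1, 1)")
  if (tp$p_zero < 0 || tp$p_zero > 1) abort("p_zero must lie in [0, 1]")
  structure(list(seed = as.integer(seed), boundary = boundary, years = years,
                 n_surveys = as.integer(n_surveys),
                 clusters_per_survey = as.integer(clusters_per_survey),
                 households_per_cluster = as.integer(households_per_cluster),
                 mean_household_size = mean_household_size,
                 resolution = resolution,
                 urban_fraction = urban_fraction,
                 protected_fraction = protected_fraction,
                 water_fraction = water_fraction,
                 n_districts_x = as.integer(n_districts_x),
                 n_districts_y = as.integer(n_districts_y),
                 temporal_order = as.integer(temporal_order),
                 missing_rate = missing_rate, species = species,
                 true_params = tp, mesh_args = mesh_args),
            class = "herd_sim_config")
}

# smooth random surface from random Fourier features; vectorized over points
smooth_field <- function(lon, lat, scale = 0.7, k = 24L) {
  a <- rnorm(k); f <- matrix(rnorm(2L * k, sd = 1 / scale), k, 2L)
  ph <- runif(k, 0, 2 * pi)
  v <- numeric(length(lon))
  for (j in seq_len(k))
    v <- v + a[j] * cos(f[j, 1] * lon + f[j, 2] * lat + ph[j])
  v / sqrt(k)
}

#' Generate aligned covariate rasters for a synthetic country
#'
#' Produces the predictor set the density model uses: binary urban/rural,
#' protected-area and water rasters, continuous elevation, plus the
#' population-density and nighttime-lights surfaces that drive the
#' urbanicity classifier. Population density and lights are constructed
#' around shared "city" peaks so they correlate positively with the urban
#' raster and the classifier is learnable. Binary fractions are met by
#' thresholding smooth fields at the requested empirical quantile.
#'
#' @param config a `herd_sim_config`.
#' @return a `herd_raster` tibble with layers `urban`, `protected`, `water`,
#'   `elevation`, `popdensity`, `nightlights`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "herd_sim_config"))
  set.seed(config$seed + 1L)
  r <- raster_grid(config$boundary, config$resolution)
  n <- nrow(r)
  bb <- bbox_of(config$boundary)
  n_city <- 3L
  cx <- runif(n_city, bb["xmin"], bb["xmax"])
  cy <- runif(n_city, bb["ymin"], bb["ymax"])
  amp <- runif(n_city, 1.5, 3)
  bump <- numeric(n)
  for (j in seq_len(n_city))
    bump <- bump + amp[j] * exp(-((r$lon - cx[j])^2 + (r$lat - cy[j])^2) / (2 * 0.12^2))
  lpop <- 2 + bump + 0.6 * smooth_field(r$lon, r$lat, scale = 0.5) +
    rnorm(n, sd = 0.25)
  r$popdensity <- exp(lpop)
  r$nightlights <- pmax(0, 2 * bump + 0.8 * smooth_field(r$lon, r$lat, scale = 0.4) +
                          rnorm(n, sd = 0.5))
  urb_score <- lpop + 0.5 * r$nightlights + rnorm(n, sd = 0.3)
  r$urban <- if (config$urban_fraction <= 0) rep(0, n) else
    as.numeric(urb_score >= quantile(urb_score, 1 - config$urban_fraction))
  prot_f <- smooth_field(r$lon, r$lat, scale = 0.35)
  r$protected <- if (config$protected_fraction <= 0) rep(0, n) else
    as.numeric(prot_f >= quantile(prot_f, 1 - config$protected_fraction))
  wat_f <- smooth_field(r$lon, r$lat, scale = 0.25)
  r$water <- if (config$water_fraction <= 0) rep(0, n) else
    as.numeric(wat_f >= quantile(wat_f, 1 - config$water_fraction))
  r$elevation <- 1000 + 350 * smooth_field(r$lon, r$lat, scale = 1) +
    120 * smooth_field(r$lon, r$lat, scale = 0.3)
  r
}

#' Simulate multi-survey cluster data from the generative density model
#'
#' Draws the latent fields (Matern spatial field via the sparse SPDE
#' precision, constrained random walk in time, iid cluster / survey / year
#' effects, separable space-time interaction), forms the cluster rates
#' `mu_i = exp(alpha0 + x_i' beta + S + omega_t + eps_i + gamma_k + eta_t +
#' u(s_i, t) + log D_i)` and draws zero-inflated Poisson counts: a
#' structural zero with probability `p_zero`, otherwise Poisson(`mu_i`).
#' All latent quantities are attached as `attr(, "latent")` for recovery
#' tests.
#'
#' @param config a `herd_sim_config`.
#' @param covariates optional covariate raster from [simulate_covariates()]
#'   (generated if omitted).
#' @param mesh optional `herd_mesh` (built from the config otherwise).
#' @return cluster tibble with columns `cluster_id`, `survey_id`, `year`,
#'   `lon`, `lat`, `district`, `urban`, `protected`, `water`, `elevation`,
#'   `livestock_count`, `human_count`, `species`.
#' @export
simulate_survey <- function(config, covariates = NULL, mesh = NULL) {
  stopifnot(inherits(config, "herd_sim_config"))
  if (is.null(covariates)) covariates <- simulate_covariates(config)
  if (is.null(mesh)) mesh <- do.call(build_mesh, c(list(config$boundary),
                                                   config$mesh_args))
  tp <- config$true_params
  bb <- bbox_of(config$boundary)
  extent <- max(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"])
  if (tp$rho_s > extent)
    warn("rho_s exceeds the boundary extent; the spatial field is near-constant")

  set.seed(config$seed + 2L)
  years <- sort(config$years)
  T_ <- length(years)
  fem <- fem_matrices(mesh)
  nv <- fem$n

  S <- if (tp$sigma_s > 0) {
    Qs <- spde_precision(fem, tp$rho_s, tp$sigma_s)$Q
    as.numeric(gmrf_sample(Qs, 1))
  } else numeric(nv)
  omega <- if (tp$sigma_rw > 0 && T_ >= config$temporal_order + 1L) {
    as.numeric(constrained_sample(rw_precision(T_, config$temporal_order)$R,
                                  tp$sigma_rw, 1))
  } else numeric(T_)
  eta_t <- if (tp$sigma_year > 0) {
    e <- rnorm(T_, 0, tp$sigma_year); e - mean(e)
  } else numeric(T_)
  gamma <- if (tp$sigma_survey > 0) rnorm(config$n_surveys, 0, tp$sigma_survey)
           else numeric(config$n_surveys)
  u <- if (tp$sigma_st > 0 && T_ > 1L) {
    Qst <- spacetime_precision(
      spde_precision(fem, tp$rho_s, tp$sigma_st)$Q, tp$rho_t, T_,
      max_dim = 5e5)
    matrix(gmrf_sample(Qst, 1), nv, T_)
  } else matrix(0, nv, T_)

  n_total <- config$n_surveys * config$clusters_per_survey
  loc <- runif_in_polygon(n_total, config$boundary)
  survey_id <- rep(seq_len(config$n_surveys), each = config$clusters_per_survey)
  year <- years[((survey_id - 1L) %% T_) + 1L]
  part <- grid_partition(config$boundary, config$n_districts_x, config$n_districts_y)
  district <- part$assign(loc[, 1], loc[, 2])
  D <- pmax(1L, rpois(n_total, config$households_per_cluster * config$mean_household_size))

  data <- tibble(
    cluster_id = seq_len(n_total),
    survey_id = survey_id,
    year = year,
    lon = loc[, 1], lat = loc[, 2],
    district = district,
    urban = raster_lookup(covariates, loc[, 1], loc[, 2], "urban"),
    protected = raster_lookup(covariates, loc[, 1], loc[, 2], "protected"),
    water = raster_lookup(covariates, loc[, 1], loc[, 2], "water"),
    elevation = raster_lookup(covariates, loc[, 1], loc[, 2], "elevation"),
    human_count = D,
    species = config$species
  )
  # the generator's linear predictor uses the standardized elevation the
  # fitted model sees, so beta["elevation"] is on the z-score scale
  elev_z <- (data$elevation - mean(data$elevation)) / max(sd(data$elevation), 1e-9)

  A <- project_points(mesh, loc)
  t_i <- match(year, years)
  eta_lin <- tp$alpha0 +
    tp$beta[["urban"]] * data$urban +
    tp$beta[["protected"]] * data$protected +
    tp$beta[["water"]] * data$water +
    tp$beta[["elevation"]] * elev_z +
    as.numeric(A %*% S) +
    omega[t_i] + eta_t[t_i] + gamma[survey_id] +
    rnorm(n_total, 0, tp$sigma_iid) +
    vapply(seq_len(n_total), function(i) sum(A[i, ] * u[, t_i[i]]), numeric(1)) +
    log(D)
  mu <- exp(eta_lin)
  structural <- runif(n_total) < tp$p_zero
  y <- ifelse(structural, 0L, rpois(n_total, mu))
  if (config$missing_rate > 0)
    y[runif(n_total) < config$missing_rate] <- NA_integer_
  data$livestock_count <- as.integer(y)

  attr(data, "latent") <- list(S = S, omega = omega, eta_t = eta_t,
                               gamma = gamma, u = u, mu = mu,
                               structural = structural, years = years,
                               mesh = mesh, covariates = covariates,
                               elev_scaling = c(center = mean(data$elevation),
                                                scale = sd(data$elevation)),
                               config = config)
  data
}

#' True density surface implied by a simulated survey's latent draws
#'
#' Evaluates the generating model's density (livestock per human, no
#' offset, no iid effects) on a prediction grid for one year, for comparing
#' predicted surfaces against the truth.
#'
#' @param sim output of [simulate_survey()].
#' @param grid prediction grid from [make_grid()].
#' @param year year to evaluate.
#' @return numeric vector of true densities per grid cell.
#' @export
true_density_surface <- function(sim, grid, year) {
  lat <- attr(sim, "latent")
  cfg <- lat$config
  tp <- cfg$true_params
  t_i <- match(year, lat$years)
  if (is.na(t_i)) abort("year outside the simulated span")
  A <- project_points(lat$mesh, cbind(grid$lon, grid$lat))
  es <- lat$elev_scaling
  elev_z <- (grid$elevation - es["center"]) / es["scale"]
  eta <- tp$alpha0 +
    tp$beta[["urban"]] * grid$urban +
    tp$beta[["protected"]] * grid$protected +
    tp$beta[["water"]] * grid$water +
    tp$beta[["elevation"]] * elev_z +
    as.numeric(A %*% lat$S) + lat$omega[t_i] + lat$eta_t[t_i] +
    as.numeric(A %*% lat$u[, t_i])
  exp(as.numeric(eta))
}

#' Simulate a weighted household census over counties
#'
#' Counties are a grid partition of the boundary. Each county has a true
#' log-density `theta_c = beta0 + S_c + e_c` with an ICAR spatial component
#' and iid noise; household livestock counts are Poisson with rate
#' `mu_c * household_size`. Households are then sampled by Poisson sampling
#' with inclusion probabilities either equal (`design = "srs"`) or
#' increasing in the household's livestock holdings
#' (`design = "informative"`, emulating a frame that oversamples livestock
#' keepers), and weights are the inverse inclusion probabilities, so the
#' Horvitz-Thompson ratio is design-unbiased while the unweighted ratio is
#' biased upward under the informative design.
#'
#' @param config a `herd_sim_config`.
#' @param n_counties_x,n_counties_y county grid dimensions.
#' @param households_per_county population size per county.
#' @param sample_fraction expected sampled fraction (1 = full census).
#' @param design `"srs"` or `"informative"`.
#' @param beta0 mean log density.
#' @param sigma_s_county,sigma_eps_county ICAR and iid standard deviations
#'   of the county effects.
#' @return household tibble (`household_id`, `county_id`, `weight`,
#'   `livestock_count`, `household_size`) with attributes `counties`
#'   (adjacency + centers), `truth` (per-county true density), and
#'   `flagged_counties` (counties with no sampled households).
#' @export
simulate_census <- function(config, n_counties_x = 8L, n_counties_y = 5L,
                            households_per_county = 400L,
                            sample_fraction = 0.05,
                            design = c("srs", "informative"),
                            beta0 = log(0.3), sigma_s_county = 0.4,
                            sigma_eps_county = 0.2) {
  stopifnot(inherits(config, "herd_sim_config"))
  design <- match.arg(design)
  set.seed(config$seed + 3L)
  part <- grid_partition(config$boundary, n_counties_x, n_counties_y)
  nc <- n_counties_x * n_counties_y
  icar <- icar_precision(part$adjacency)
  S <- if (sigma_s_county > 0)
    as.numeric(constrained_sample(icar$Q, sigma_s_county, 1)) else numeric(nc)
  eps <- rnorm(nc, 0, sigma_eps_county)
  theta <- beta0 + S + eps
  mu_c <- exp(theta)

  hh <- purrr::map_dfr(seq_len(nc), function(cid) {
    size <- 1L + rpois(households_per_county, config$mean_household_size - 1)
    tibble(county_id = cid,
           household_size = size,
           livestock_count = rpois(households_per_county, mu_c[cid] * size))
  })
  hh$household_id <- seq_len(nrow(hh))
  if (design == "srs") {
    pi_i <- rep(min(1, sample_fraction), nrow(hh))
  } else {
    score <- 1 + 2 * pmin(hh$livestock_count, 10)
    pi_i <- pmin(1, sample_fraction * score / mean(score))
  }
  sampled <- runif(nrow(hh)) < pi_i
  out <- hh[sampled, ]
  out$weight <- 1 / pi_i[sampled]
  out <- out[, c("household_id", "county_id", "weight", "livestock_count",
                 "household_size")]
  missing_counties <- setdiff(seq_len(nc), unique(out$county_id))
  if (length(missing_counties))
    inform(paste0("counties with no sampled households: ",
                  paste(missing_counties, collapse = ", ")))
  attr(out, "counties") <- list(adjacency = part$adjacency,
                                centers = part$centers)
  attr(out, "truth") <- tibble(county_id = seq_len(nc), mu_true = mu_c,
                               theta_true = theta)
  attr(out, "flagged_counties") <- missing_counties
  out
}

#' Write simulated tables to CSV
#' @param data cluster or household tibble.
#' @param path output path.
#' @export
write_records_csv <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}
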