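# fixtures are built once per run and cached; everything is generated in code
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

test_mesh <- function() fixture("mesh", function()
  build_mesh(square_boundary(0, 0, 2, 2), 0.3, 0.6, 1.0))

fine_mesh <- function() fixture("fine_mesh", function()
  build_mesh(square_boundary(0, 0, 2, 2), 0.12, 0.6, 1.0))

# restricted-model simulation used by several files: one survey per year,
# spatial + temporal + nugget effects only
restricted_config <- function(seed = 7, true_params = list(), ...) {
  base <- list(sigma_survey = 0, sigma_year = 0, sigma_st = 0)
  synthetic_config(seed = seed,
                   true_params = utils::modifyList(base, true_params),
                   ...)
}

test_sim <- function() fixture("sim", function() {
  cfg <- restricted_config()
  covs <- simulate_covariates(cfg)
  mesh <- build_mesh(cfg$boundary, 0.25, 0.6, 1.0)
  list(cfg = cfg, covs = covs, mesh = mesh,
       data = simulate_survey(cfg, covs, mesh))
})

# a single right triangle as a minimal mesh-like object for FEM checks
unit_right_triangle <- function() {
  list(vertices = cbind(lon = c(0, 1, 0), lat = c(0, 0, 1)),
       triangles = matrix(c(1L, 2L, 3L), 1L, 3L))
}

# closed-form Matern (nu = 1) correlation at distance h for range rho
matern1_cor <- function(h, rho) {
  kd <- sqrt(8) * h / rho
  ifelse(h == 0, 1, kd * besselK(kd, 1))
}
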