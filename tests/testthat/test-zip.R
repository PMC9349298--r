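test_that("ZIP log-likelihood matches direct evaluation and its limits", {
  expect_equal(zip_loglik(0, 1, 0.5), log(0.5 + 0.5 * exp(-1)))
  # p = 0 collapses to the Poisson log-pmf for all y
  y <- c(0, 1, 2, 7, 30)
  expect_equal(zip_loglik(y, 3.2, 0), dpois(y, 3.2, log = TRUE))
  # p = 1: certain zero
  expect_equal(zip_loglik(0, 2, 1), 0)
  expect_identical(zip_loglik(3, 2, 1), -Inf)
  expect_error(zip_loglik(-1, 1, 0.5), "non-negative")
  expect_error(zip_loglik(1.5, 1, 0.5), "non-negative integers")
  expect_error(zip_loglik(1, -2, 0.5), "mu")
})

test_that("ZIP log-likelihood is numerically stable at extreme rates", {
  expect_equal(zip_loglik(0, 1e6, 0.5), log(0.5))
  expect_true(is.finite(zip_loglik(1e6, 1e6, 0.5)))
  expect_true(is.finite(zip_loglik(0, 1e-12, 0.999)))
})

test_that("linear predictor includes exactly the enabled terms", {
  spec <- model_spec(1, restricted = TRUE)
  spec$effects$spde <- FALSE; spec$effects$rw <- FALSE
  spec$effects$iid_cluster <- FALSE
  d <- tibble::tibble(lon = 0.5, lat = 0.5, year = 2006L, survey_id = 1L,
                      human_count = 7L)
  mu <- linear_predictor(spec, d, list(alpha0 = 0))
  expect_equal(mu, 7)
  d2 <- d; d2$human_count <- 14L
  expect_equal(linear_predictor(spec, d2, list(alpha0 = 0)), 14)
  # model 1 vs model 2 on the same state differ only through the urban term
  s1 <- model_spec(1, restricted = TRUE); s2 <- model_spec(2, restricted = TRUE)
  s1$effects$spde <- s2$effects$spde <- FALSE
  s1$effects$rw <- s2$effects$rw <- FALSE
  s1$effects$iid_cluster <- s2$effects$iid_cluster <- FALSE
  dd <- tibble::tibble(lon = c(0.2, 0.8), lat = 0.5, year = 2006L,
                       survey_id = 1L, human_count = 10L, urban = c(0, 1))
  st <- list(alpha0 = -1, beta = list(urban = 0.7))
  mu1 <- linear_predictor(s1, dd, st)
  mu2 <- linear_predictor(s2, dd, st)
  expect_equal(mu2 / mu1, exp(0.7 * dd$urban))
  # a missing covariate value is reported with the cluster
  dd$urban[2] <- NA
  expect_error(linear_predictor(s2, dd, st), "row 2")
})

test_that("the model menu maps ids to the published fixed-effect sets", {
  expect_equal(model_spec(1)$fixed_effects, "intercept")
  expect_equal(model_spec(2)$fixed_effects, c("intercept", "urban"))
  expect_equal(model_spec(5)$fixed_effects,
               c("intercept", "urban", "protected", "water", "elevation"))
  expect_equal(model_spec(6)$fixed_effects, model_spec(5)$fixed_effects)
  expect_equal(model_spec(6)$temporal_order, 1L)
  expect_equal(model_spec(5)$temporal_order, 2L)
  drc <- model_spec("drc_restricted")
  expect_false(drc$effects$spacetime)
  expect_false(drc$effects$iid_survey)
  expect_false(drc$effects$iid_year)
  expect_true(drc$effects$spde && drc$effects$rw && drc$effects$iid_cluster)
  expect_error(model_spec(7), "model")
})

test_that("posterior mean of the intercept matches a dense quadrature oracle", {
  # 30 clusters, one year, intercept-only Poisson: the exact posterior of
  # alpha0 is one-dimensional and integrable by quadrature
  set.seed(101)
  n <- 30L
  D <- rpois(n, 80) + 1L
  alpha_true <- -1.3
  y <- rpois(n, D * exp(alpha_true))
  d <- tibble::tibble(cluster_id = 1:n, survey_id = 1L, year = 2006L,
                      lon = runif(n, 0.2, 1.8), lat = runif(n, 0.2, 1.8),
                      human_count = D, livestock_count = y)
  spec <- model_spec(1, restricted = TRUE)
  spec$effects$spde <- FALSE; spec$effects$rw <- FALSE
  spec$effects$iid_cluster <- FALSE
  fit <- fit_zip_model(d, test_mesh(), spec,
                       control = fit_control(fix_p = 0, seed = 2))
  dr <- posterior_sample(fit, n = 2000, seed = 3)
  a_draws <- draws_block(dr, "fixed")[, 1]
  # oracle: exact likelihood x N(0, 1000) prior on a dense grid
  logpost <- function(a) sum(dpois(y, D * exp(a), log = TRUE)) +
    dnorm(a, 0, sqrt(1000), log = TRUE)
  grid <- seq(alpha_true - 1, alpha_true + 1, length.out = 4001)
  w <- exp(vapply(grid, logpost, numeric(1)))
  oracle_mean <- sum(grid * w) / sum(w)
  expect_lt(abs(mean(a_draws) - oracle_mean), 0.05)
})

test_that("the structural-zero probability concentrates when absent", {
  cfg <- restricted_config(seed = 41, clusters_per_survey = 70L,
                           n_surveys = 3L, years = 2006:2008,
                           true_params = list(p_zero = 0, sigma_rw = 0.1))
  sim <- simulate_survey(cfg)
  mesh <- build_mesh(cfg$boundary, 0.35, 0.7, 0.8)
  fit <- suppressWarnings(
    fit_zip_model(sim, mesh, model_spec(2, restricted = TRUE),
                  control = fit_control(iter = 220, warmup = 90, seed = 5)))
  expect_lt(median(fit$chain$p), 0.1)
})

test_that("spatially shuffled data act as a negative control", {
  # without a nugget the field must explain all extra-Poisson variation, so
  # destroying the spatial arrangement forces it toward iid-like behaviour:
  # a much shorter range than on the intact data
  sim <- test_sim()
  one <- sim$data[sim$data$survey_id == 1, ]
  spec <- model_spec(2, restricted = TRUE)
  spec$effects$rw <- FALSE
  spec$effects$iid_cluster <- FALSE
  ctrl <- fit_control(method = "map", seed = 8, map_maxit = 250, fix_p = 0.1)
  fit_true <- suppressWarnings(fit_zip_model(one, sim$mesh, spec,
                                             control = ctrl))
  shuffled <- one
  set.seed(99)
  perm <- sample.int(nrow(shuffled))
  shuffled$lon <- shuffled$lon[perm]
  shuffled$lat <- shuffled$lat[perm]
  fit_shuf <- suppressWarnings(fit_zip_model(shuffled, sim$mesh, spec,
                                             control = ctrl))
  expect_lt(fit_shuf$chain$rho_s[1], fit_true$chain$rho_s[1])
})

test_that("posterior_sample defaults, determinism, and iid exclusion", {
  sim <- test_sim()
  fit <- fixture("map_fit", function()
    suppressWarnings(fit_zip_model(sim$data, sim$mesh,
                                   model_spec(2, restricted = TRUE),
                                   control = fit_control(method = "map", seed = 4))))
  dr <- posterior_sample(fit, seed = 6)
  expect_equal(dr$n, 1000L)   # default draw count
  dr2 <- posterior_sample(fit, seed = 6)
  expect_identical(dr$latent, dr2$latent)
  expect_false(any(dr$blocks$block %in% c("eps", "gamma", "eta")))
  dr_iid <- posterior_sample(fit, n = 50, seed = 6, include_iid = TRUE)
  expect_true("eps" %in% dr_iid$blocks$block)
  expect_error(posterior_sample(fit, n = 0), "positive")
  # hyperparameter draws are within [0,1] for p and positive for scales
  expect_true(all(dr$hyper$p >= 0 & dr$hyper$p <= 1))
  expect_true(all(dr$hyper$sigma_s > 0))
})

test_that("enabling one effect leaves other blocks' bookkeeping unchanged", {
  sim <- test_sim()
  pr <- default_priors()
  ctl <- fit_control()
  md_a <- herdmaps:::build_model_data(model_spec(2, restricted = TRUE),
                                      sim$data, sim$mesh, pr, ctl)
  spec_b <- model_spec(2, restricted = TRUE)
  spec_b$effects$iid_year <- TRUE
  md_b <- herdmaps:::build_model_data(spec_b, sim$data, sim$mesh, pr, ctl)
  shared <- intersect(md_a$blocks$block, md_b$blocks$block)
  expect_equal(md_a$blocks$size[match(shared, md_a$blocks$block)],
               md_b$blocks$size[match(shared, md_b$blocks$block)])
  expect_equal(ncol(md_b$M) - ncol(md_a$M), md_b$T)
})

test_that("temporal effects demand at least two years of data", {
  sim <- test_sim()
  one_year <- sim$data[sim$data$year == 2006, ]
  expect_error(fit_zip_model(one_year, sim$mesh, model_spec(2, restricted = TRUE)),
               "fewer than 2 years")
})

test_that("simulation-based calibration holds on the intercept + nugget model", {
  # draw (alpha0, sigma_eps) from the priors the model itself uses, simulate,
  # refit, and rank the true sigma_eps among thinned posterior draws; ranks
  # must be uniform if the approximate posterior is calibrated
  n_rep <- 200L
  L <- 19L
  n <- 40L
  pr <- default_priors()
  pr$fixed_sd <- 1
  ranks <- integer(n_rep)
  set.seed(1234)
  seeds <- sample.int(1e6, n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(seeds[r])
    a0 <- rnorm(1, 0, 1)
    s_eps <- pr$iid$quantile(runif(1))
    eps <- rnorm(n, 0, s_eps)
    D <- rep(50L, n)
    y <- rpois(n, D * exp(a0 + eps))
    d <- tibble::tibble(cluster_id = 1:n, survey_id = 1L, year = 2006L,
                        lon = runif(n, 0.3, 1.7), lat = runif(n, 0.3, 1.7),
                        human_count = D, livestock_count = y)
    spec <- model_spec(1, restricted = TRUE)
    spec$effects$spde <- FALSE; spec$effects$rw <- FALSE
    fit <- suppressWarnings(
      fit_zip_model(d, test_mesh(), spec, priors = pr,
                    control = fit_control(iter = 200, warmup = 30,
                                          fix_p = 0, seed = seeds[r])))
    thin <- fit$chain$sigma_eps[round(seq(1, nrow(fit$chain), length.out = L))]
    ranks[r] <- sum(thin < s_eps)
  }
  # coarse uniformity check: chi-square over 10 bins at alpha = 0.01
  bins <- cut(ranks, breaks = seq(-0.5, L + 0.5, length.out = 11))
  chi <- sum((table(bins) - n_rep / 10)^2 / (n_rep / 10))
  expect_lt(chi, qchisq(0.99, df = 9))
})
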