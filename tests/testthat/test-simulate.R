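test_that("a fixed seed reproduces identical tables", {
  cfg <- restricted_config(seed = 31, clusters_per_survey = 20L, n_surveys = 2L,
                           years = 2006:2007)
  a <- simulate_survey(cfg)
  b <- simulate_survey(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  ca <- simulate_covariates(cfg)
  cb <- simulate_covariates(cfg)
  expect_identical(as.data.frame(ca), as.data.frame(cb))
})

test_that("covariate rasters are aligned, binary where promised, learnable", {
  cfg <- restricted_config(seed = 5)
  r <- simulate_covariates(cfg)
  expect_true(all(r$urban %in% c(0, 1)))
  expect_true(all(r$protected %in% c(0, 1)))
  expect_true(all(r$water %in% c(0, 1)))
  expect_true(all(r$popdensity > 0))
  # urbanicity classifier learnability: covariates separate the classes
  expect_gt(cor(log(r$popdensity), r$urban), 0.2)
  expect_gt(cor(r$nightlights, r$urban), 0.2)
})

test_that("raster dimensions follow ceil(extent/resolution)", {
  cfg <- synthetic_config(seed = 1, boundary = square_boundary(0, 0, 1, 1),
                          resolution = 0.017)
  r <- simulate_covariates(cfg)
  expect_identical(attr(r, "ncol"), 59L)
  expect_identical(attr(r, "nrow"), 59L)
})

test_that("binary fraction requests are honoured at many cells", {
  cfg <- synthetic_config(seed = 9, boundary = square_boundary(0, 0, 1, 1),
                          resolution = 0.01, protected_fraction = 0.2)
  r <- simulate_covariates(cfg)
  expect_gte(nrow(r), 1e4)
  expect_lt(abs(mean(r$protected) - 0.2), 0.05)
})

test_that("an all-rural configuration yields an identically zero urban raster", {
  cfg <- synthetic_config(seed = 2, urban_fraction = 0)
  r <- simulate_covariates(cfg)
  expect_true(all(r$urban == 0))
})

test_that("p_zero = 1 produces only structural zeros", {
  cfg <- restricted_config(seed = 11, clusters_per_survey = 30L, n_surveys = 2L,
                           years = 2006:2007, true_params = list(p_zero = 1))
  sim <- simulate_survey(cfg)
  expect_true(all(sim$livestock_count == 0))
})

test_that("with all effects off the offset drives the mean count", {
  cfg <- synthetic_config(seed = 13, clusters_per_survey = 400L, n_surveys = 1L,
                          years = 2006L, households_per_cluster = 2L,
                          mean_household_size = 5,
                          true_params = list(alpha0 = 0, p_zero = 0,
                                             sigma_s = 0, sigma_rw = 0,
                                             sigma_iid = 0, sigma_survey = 0,
                                             sigma_year = 0, sigma_st = 0,
                                             beta = c(urban = 0, protected = 0,
                                                      water = 0, elevation = 0)))
  sim <- simulate_survey(cfg)
  # mu_i = D_i with E(D) = 10, so mean count is about 10
  expect_equal(mean(sim$livestock_count), 10, tolerance = 0.1)
})

test_that("the ZIP zero-fraction identity holds", {
  for (p0 in c(0.05, 0.3)) {
    cfg <- restricted_config(seed = 17 + round(100 * p0),
                             clusters_per_survey = 1000L, n_surveys = 5L,
                             households_per_cluster = 3L,
                             true_params = list(p_zero = p0, alpha0 = -2.5,
                                                sigma_survey = 0, sigma_year = 0,
                                                sigma_st = 0))
    sim <- simulate_survey(cfg)
    mu <- attr(sim, "latent")$mu
    expected <- p0 + (1 - p0) * mean(exp(-mu))
    obs <- mean(sim$livestock_count == 0)
    mc_err <- 3 * sqrt(expected * (1 - expected) / nrow(sim))
    expect_lt(abs(obs - expected), mc_err + 0.01)
  }
})

test_that("a range beyond the boundary extent triggers a warning", {
  cfg <- restricted_config(seed = 19, clusters_per_survey = 10L, n_surveys = 2L,
                           years = 2006:2007, true_params = list(rho_s = 5))
  expect_warning(simulate_survey(cfg), "near-constant")
})

test_that("the simulated latent field has an increasing variogram up to the range", {
  sim <- test_sim()
  fem <- fem_matrices(sim$mesh)
  Q <- spde_precision(fem, 0.5, 1)$Q
  set.seed(4)
  draws <- gmrf_sample(Q, 2000)
  v <- sim$mesh$vertices
  inner <- which(point_in_polygon(v[, 1], v[, 2], square_boundary(0.3, 0.3, 1.4, 1.4)))
  d <- as.matrix(dist(v[inner, ]))
  semiv <- function(lo, hi) {
    pairs <- which(d > lo & d <= hi & upper.tri(d), arr.ind = TRUE)
    pairs <- pairs[seq_len(min(nrow(pairs), 400L)), , drop = FALSE]
    mean(vapply(seq_len(nrow(pairs)), function(k) {
      i <- inner[pairs[k, 1]]; j <- inner[pairs[k, 2]]
      mean((draws[i, ] - draws[j, ])^2) / 2
    }, numeric(1)))
  }
  bins <- cbind(c(0.15, 0.25, 0.35, 0.45), c(0.25, 0.35, 0.45, 0.55))
  gam <- vapply(seq_len(nrow(bins)), function(b) semiv(bins[b, 1], bins[b, 2]),
                numeric(1))
  # monotone increase up to ~rho_s, with 10% slack per step
  expect_true(all(diff(gam) > -0.1 * gam[-length(gam)]))
  expect_gt(gam[4], gam[1])
})

test_that("missingness is applied at the configured rate", {
  cfg <- restricted_config(seed = 23, clusters_per_survey = 500L, n_surveys = 2L,
                           years = 2006:2007, missing_rate = 0.2)
  sim <- simulate_survey(cfg)
  expect_lt(abs(mean(is.na(sim$livestock_count)) - 0.2), 0.05)
})

test_that("equal-probability census sampling gives equal weights", {
  cfg <- restricted_config(seed = 3)
  hh <- simulate_census(cfg, sample_fraction = 0.1, design = "srs")
  expect_equal(length(unique(hh$weight)), 1L)
})

test_that("a full census returns the population ratio exactly", {
  cfg <- restricted_config(seed = 29)
  hh <- simulate_census(cfg, n_counties_x = 2L, n_counties_y = 2L,
                        households_per_county = 200L, sample_fraction = 1)
  est <- ht_ratio(hh)
  pop <- hh |>
    dplyr::group_by(county_id) |>
    dplyr::summarise(r = sum(livestock_count) / sum(household_size))
  expect_equal(est$mu_hat, pop$r, tolerance = 1e-12)
})

test_that("weights correct informative sampling bias", {
  # 200 replicate censuses: the unweighted ratio is biased upward under
  # livestock-dependent inclusion; the Horvitz-Thompson ratio is not
  err_w <- err_u <- numeric(200)
  for (k in 1:200) {
    cfg <- restricted_config(seed = 1000 + k)
    hh <- simulate_census(cfg, n_counties_x = 2L, n_counties_y = 2L,
                          households_per_county = 150L, sample_fraction = 0.15,
                          design = "informative")
    truth <- attr(hh, "truth")
    est <- ht_ratio(hh)
    unw <- hh |>
      dplyr::group_by(county_id) |>
      dplyr::summarise(r = sum(livestock_count) / sum(household_size))
    m <- match(est$county_id, truth$county_id)
    err_w[k] <- mean(est$mu_hat - truth$mu_true[m])
    err_u[k] <- mean(unw$r[match(est$county_id, unw$county_id)] -
                       truth$mu_true[m])
  }
  expect_gt(mean(err_u), 0.05)          # clear upward bias
  expect_lt(abs(mean(err_w)), 0.02)     # design-unbiased
  expect_lt(abs(mean(err_w)), mean(err_u) / 3)
})

test_that("counties with no sampled households are flagged", {
  cfg <- restricted_config(seed = 37)
  expect_message(
    hh <- simulate_census(cfg, n_counties_x = 4L, n_counties_y = 4L,
                          households_per_county = 30L,
                          sample_fraction = 0.01),
    "no sampled households")
  expect_true(length(attr(hh, "flagged_counties")) > 0)
})
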