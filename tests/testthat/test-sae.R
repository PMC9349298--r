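test_that("the weighted ratio matches hand computation and its invariances", {
  hh <- tibble::tibble(household_id = 1:2, county_id = 1L, weight = c(2, 3),
                       livestock_count = c(4, 0), household_size = c(5, 5))
  expect_equal(ht_ratio(hh)$mu_hat, 0.32)
  # equal weights reduce to the unweighted ratio
  hh2 <- tibble::tibble(household_id = 1:3, county_id = 1L, weight = 5,
                        livestock_count = c(2, 0, 7), household_size = c(4, 6, 5))
  expect_equal(ht_ratio(hh2)$mu_hat, 9 / 15)
  # a single household returns its own ratio
  hh3 <- tibble::tibble(household_id = 1L, county_id = 1L, weight = 2.5,
                        livestock_count = 3, household_size = 6)
  expect_equal(ht_ratio(hh3)$mu_hat, 0.5)
  # invariant to rescaling all weights
  hh4 <- hh; hh4$weight <- hh$weight * 37.5
  expect_equal(ht_ratio(hh4)$mu_hat, ht_ratio(hh)$mu_hat)
  expect_error(ht_ratio(dplyr::mutate(hh, weight = -1)), "weights")
})

test_that("design variance vanishes for identical households and flags singletons", {
  same <- tibble::tibble(household_id = 1:5, county_id = 1L, weight = 2,
                         livestock_count = 3, household_size = 5)
  expect_equal(design_variance(same)$var_hat, 0)
  single <- tibble::tibble(household_id = 1L, county_id = 1L, weight = 1,
                           livestock_count = 2, household_size = 4)
  expect_warning(dv <- design_variance(single), "single household")
  expect_true(is.na(dv$var_hat))
  expect_true(dv$unstable)
})

test_that("the linearized variance agrees with a delete-one jackknife", {
  set.seed(7)
  n <- 50
  hh <- tibble::tibble(household_id = seq_len(n), county_id = 1L,
                       weight = runif(n, 1, 3),
                       household_size = 1L + rpois(n, 4),
                       livestock_count = rpois(n, 1.2 * (1L + rpois(n, 4))))
  v_lin <- design_variance(hh)$var_hat
  mu_i <- vapply(seq_len(n), function(i) ht_ratio(hh[-i, ])$mu_hat, numeric(1))
  v_jk <- (n - 1) / n * sum((mu_i - mean(mu_i))^2)
  expect_lt(abs(v_lin - v_jk) / v_jk, 0.1)
})

test_that("the design variance scales as 1/n under iid replication", {
  set.seed(21)
  sizes <- c(25, 50, 100, 200, 400)
  vbar <- vapply(sizes, function(n) {
    mean(replicate(30, {
      hh <- tibble::tibble(household_id = seq_len(n), county_id = 1L,
                           weight = 1,
                           household_size = 1L + rpois(n, 4),
                           livestock_count = rpois(n, 0.4 * (1L + rpois(n, 4))))
      design_variance(hh)$var_hat
    }))
  }, numeric(1))
  slope <- coef(lm(log(vbar) ~ log(sizes)))[2]
  expect_lt(abs(slope + 1), 0.15)
})

test_that("the delta-method log transform gives the worked values", {
  lt <- log_transform(0.32, 0.01)
  expect_equal(lt$theta_hat, -1.1394, tolerance = 1e-4)
  expect_equal(lt$V, 0.09766, tolerance = 1e-4)
  expect_equal(log_transform(0.32, 0)$V, 0)
  lt1 <- log_transform(1, 0.2)
  expect_equal(lt1$theta_hat, 0)
  expect_equal(lt1$V, 0.2)
  expect_warning(lt0 <- log_transform(0, 0.1), "zero")
  expect_true(is.na(lt0$theta_hat))
})

chain_adjacency <- function(n) {
  a <- matrix(0, n, n)
  a[cbind(1:(n - 1), 2:n)] <- 1
  a + t(a)
}

test_that("with tiny design variance the smoother interpolates the direct estimates", {
  n <- 10
  set.seed(5)
  theta <- rnorm(n, log(0.5), 0.4)
  est <- tibble::tibble(county_id = 1:n, mu_hat = exp(theta),
                        var_hat = 1e-9, theta_hat = theta, V = 1e-8,
                        n_households = 100L, unstable = FALSE, missing = FALSE)
  sm <- smooth_areas(est, chain_adjacency(n), seed = 2,
                     iter = 600, warmup = 200)
  expect_lt(max(abs(sm$median - est$mu_hat)), 0.01)
})

test_that("counties without data shrink to the neighbour-informed prediction", {
  n <- 12
  set.seed(6)
  # smooth spatial gradient in the truth
  theta <- log(0.3) + seq(-0.6, 0.6, length.out = n)
  est <- tibble::tibble(county_id = 1:n, mu_hat = exp(theta),
                        var_hat = 0.001, theta_hat = theta,
                        V = 0.001 / exp(theta)^2,
                        n_households = 50L, unstable = FALSE, missing = FALSE)
  est$theta_hat[6] <- NA; est$V[6] <- NA; est$missing[6] <- TRUE
  sm <- smooth_areas(est, chain_adjacency(n), seed = 3,
                     iter = 800, warmup = 300)
  expect_true(sm$missing[6])
  # the gap county is predicted between its neighbours' values
  expect_gt(sm$median[6], sm$median[4] * 0.8)
  expect_lt(sm$median[6], sm$median[9] * 1.2)
})

test_that("the intercept tracks the precision-weighted mean absent spatial signal", {
  n <- 15
  set.seed(8)
  V <- runif(n, 0.01, 0.2)
  theta <- rnorm(n, log(0.4), sqrt(V))
  est <- tibble::tibble(county_id = 1:n, mu_hat = exp(theta),
                        var_hat = V * exp(theta)^2, theta_hat = theta, V = V,
                        n_households = 30L, unstable = FALSE, missing = FALSE)
  sm <- smooth_areas(est, chain_adjacency(n), seed = 4, iter = 800,
                     warmup = 300)
  dec <- attr(sm, "decomposition")
  wmean <- sum(theta / V) / sum(1 / V)
  expect_lt(abs(dec$beta0 - wmean), 0.15)
  # sum-to-zero on the ICAR component
  expect_lt(abs(sum(dec$S_mean)), 0.05)
})

test_that("smoothing refuses unusable input", {
  est <- tibble::tibble(county_id = 1:3, mu_hat = NA_real_, var_hat = NA_real_,
                        theta_hat = NA_real_, V = NA_real_, n_households = 0L,
                        unstable = TRUE, missing = TRUE)
  expect_error(smooth_areas(est, chain_adjacency(3)), "no usable")
})
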