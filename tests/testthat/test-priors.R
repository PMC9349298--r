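test_that("PC prior for a standard deviation is a calibrated exponential", {
  pr <- pc_sd(1, 0.05)
  expect_equal(pr$lambda, -log(0.05), tolerance = 1e-12)
  expect_equal(pr$lambda, 2.9957, tolerance = 1e-4)
  expect_equal(pr$cdf(1), 0.95, tolerance = 1e-12)
  # flat limit
  expect_lt(pc_sd(1, 0.999)$lambda, 0.002)
  expect_error(pc_sd(-1, 0.05), "U")
  expect_error(pc_sd(1, 1.2), "alpha")
  # density integrates to one
  expect_equal(integrate(function(s) exp(pr$logpdf(s)), 0, Inf)$value, 1,
               tolerance = 1e-8)
})

test_that("variance-threshold calibration converts to the sigma scale", {
  pr <- pc_sd_from_variance_bound(0.5, 0.01)
  expect_equal(pr$lambda, -log(0.01) / sqrt(0.5), tolerance = 1e-12)
  expect_equal(pr$lambda, 6.5127, tolerance = 1e-4)
  # P(sigma^2 > 0.5) = P(sigma > sqrt(0.5)) = 0.01 by closed form
  expect_equal(1 - pr$cdf(sqrt(0.5)), 0.01, tolerance = 1e-10)
  pr1 <- pc_sd_from_variance_bound(1, 0.03)
  expect_equal(pr1$lambda, pc_sd(1, 0.03)$lambda)
})

test_that("joint Matern PC prior reproduces its calibration statements", {
  pr <- pc_matern(0.3, 0.05, 1, 0.05)
  expect_equal(pr$lambda_rho, -log(0.05) * 0.3, tolerance = 1e-12)
  expect_equal(pr$lambda_rho, 0.8987, tolerance = 1e-4)
  # numeric integral of the range marginal below the threshold
  mass <- integrate(function(r) exp(pr$logpdf_rho(r)), 0, 0.3,
                    rel.tol = 1e-10)$value
  expect_equal(mass, 0.05, tolerance = 1e-6)
  expect_equal(pr$cdf_rho(0.3), 0.05, tolerance = 1e-12)
  # the sigma marginal factorizes as pc_sd(1, 0.05)
  ss <- seq(0.01, 4, by = 0.07)
  expect_equal(pr$sigma_prior$logpdf(ss), pc_sd(1, 0.05)$logpdf(ss))
  # joint density integrates to 1
  total <- integrate(function(r) exp(pr$logpdf_rho(r)), 0, Inf)$value
  expect_equal(total, 1, tolerance = 1e-4)
})

test_that("AR1 PC prior is calibrated and normalized on (-1, 1)", {
  pr <- pc_ar1(0.5, 0.8, base_model = "cor1")
  tail_num <- integrate(function(r) exp(pr$logpdf(r)), 0.5, 1,
                        rel.tol = 1e-10)$value
  expect_equal(tail_num, 0.8, tolerance = 1e-4)
  expect_equal(pr$tail_prob(0.5), 0.8, tolerance = 1e-10)
  total <- integrate(function(r) exp(pr$logpdf(r)), -1, 1,
                     rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)
  # median calibration: tail probability at the prior median is one half
  med <- uniroot(function(q) pr$tail_prob(q) - 0.5, c(-0.999, 0.999))$root
  pr_med <- pc_ar1(med, 0.5, base_model = "cor1")
  expect_equal(pr_med$tail_prob(med), 0.5, tolerance = 1e-8)
  # infeasible tail statements are refused (cor1 base cannot push mass away
  # from the base model below the flat-limit tail)
  expect_error(pc_ar1(0.5, 0.2, base_model = "cor1"), "infeasible")
})

test_that("cor0 base model is symmetric and calibrated", {
  pr <- pc_ar1(0.5, 0.2, base_model = "cor0")
  expect_equal(integrate(function(r) exp(pr$logpdf(r)), 0.5, 1,
                         rel.tol = 1e-5)$value, 0.2, tolerance = 2e-4)
  expect_equal(integrate(function(r) exp(pr$logpdf(r)), -1, 0,
                         rel.tol = 1e-5)$value +
                 integrate(function(r) exp(pr$logpdf(r)), 0, 1,
                           rel.tol = 1e-5)$value, 1, tolerance = 5e-4)
  expect_error(pc_ar1(0.5, 0.8, base_model = "cor0"), "infeasible")
})

test_that("log-gamma precision prior integrates to one over sigma", {
  pr <- prior_gamma_precision(1, 5e-5)
  expect_equal(integrate(function(s) exp(pr$logpdf(s)), 0, Inf,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-5)
})

test_that("Monte Carlo and quadrature rate-ratio intervals agree", {
  pr <- pc_sd(1, 0.05)
  q_mc <- implied_rate_ratio_interval(pr, n_draws = 1e6, seed = 11, method = "mc")
  q_quad <- implied_rate_ratio_interval(pr, method = "quadrature")
  expect_lt(max(abs(q_mc - q_quad)), 0.02)
  # interval is symmetric on the log scale (theta symmetric about 0)
  expect_equal(q_quad[["lower"]] * q_quad[["upper"]], 1, tolerance = 0.01)
})

test_that("degenerate and invalid rate-ratio requests behave", {
  # sigma concentrated at zero: exp(theta) degenerates to 1
  tiny <- pc_sd(1e-9, 0.05)
  q <- implied_rate_ratio_interval(tiny, method = "quadrature")
  expect_equal(unname(q), c(1, 1), tolerance = 1e-3)
  expect_error(implied_rate_ratio_interval(pc_sd(1, 0.05), n_draws = 100,
                                           method = "mc"), "1e6")
  expect_error(implied_rate_ratio_interval(pc_sd(1, 0.05), level = 1.2),
               "level")
})
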