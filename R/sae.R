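#' Horvitz-Thompson ratio estimates of county density
#'
#' Weighted ratio of the estimated livestock total to the estimated human
#' population per county: `mu_hat_c = sum(w Y) / sum(w D)` with weights the
#' inverse sampling probabilities. Invariant to rescaling all weights by a
#' constant.
#'
#' @param households tibble with `county_id`, `weight`, `livestock_count`,
#'   `household_size` (the human count per household).
#' @return tibble `county_id`, `mu_hat`, `n_households`.
#' @export
ht_ratio <- function(households) {
  h <- as_tibble(households)
  if (any(h$weight <= 0)) abort("all weights must be > 0")
  out <- h |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(
      Y_ht = sum(.data$weight * .data$livestock_count),
      D_ht = sum(.data$weight * .data$household_size),
      n_households = dplyr::n(), .groups = "drop")
  if (any(out$D_ht == 0)) abort("county with zero weighted human total")
  out |>
    dplyr::mutate(mu_hat = .data$Y_ht / .data$D_ht) |>
    dplyr::select("county_id", "mu_hat", "n_households")
}

#' Design-based variance of the county ratio estimates
#'
#' Taylor-linearized variance of the ratio under with-replacement sampling
#' of households: with residuals `e_i = Y_i - mu_hat D_i`,
#' `var(mu_hat) = n/(n-1) * sum_i (w_i e_i - mean(w e))^2 / (sum w D)^2`.
#' Counties with a single household are flagged and their variance set
#' missing. The design details of the census extract are not published, so
#' the with-replacement household-level linearization is the documented
#' assumption; it is cross-checked against a delete-one jackknife in the
#' test suite.
#'
#' @inheritParams ht_ratio
#' @return tibble `county_id`, `mu_hat`, `var_hat`, `n_households`,
#'   `unstable` (TRUE where n < 2).
#' @export
design_variance <- function(households) {
  h <- as_tibble(households)
  est <- ht_ratio(h)
  v <- h |>
    dplyr::left_join(est, by = "county_id") |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(var_hat = {
      n <- dplyr::n()
      if (n < 2L) NA_real_ else {
        we <- .data$weight * (.data$livestock_count - .data$mu_hat[1] * .data$household_size)
        Dht <- sum(.data$weight * .data$household_size)
        n / (n - 1) * sum((we - mean(we))^2) / Dht^2
      }
    }, .groups = "drop")
  out <- dplyr::left_join(est, v, by = "county_id") |>
    dplyr::mutate(unstable = is.na(.data$var_hat)) |>
    dplyr::select("county_id", "mu_hat", "var_hat", "n_households", "unstable")
  if (any(out$unstable))
    warn(paste0(sum(out$unstable), " county(ies) with a single household; ",
                "variance set missing"))
  out
}

#' Delta-method log transform of a ratio estimate
#'
#' `theta_hat = log(mu_hat)` with asymptotic variance
#' `V = var_hat / mu_hat^2`, so that
#' `theta_hat | mu_hat ~ N(log(mu_hat), var(mu_hat)/mu_hat^2)`.
#'
#' @param mu_hat ratio estimate(s), > 0 for a finite log.
#' @param var_hat design variance(s).
#' @return tibble `theta_hat`, `V`; rows with `mu_hat = 0` carry NA and
#'   must be excluded from the smoothing likelihood.
#' @export
log_transform <- function(mu_hat, var_hat) {
  bad <- mu_hat == 0
  if (any(bad, na.rm = TRUE))
    warn(paste0(sum(bad), " estimate(s) are exactly zero: no finite log; ",
                "excluded from smoothing"))
  tibble(theta_hat = ifelse(bad, NA_real_, log(mu_hat)),
         V = ifelse(bad, NA_real_, var_hat / mu_hat^2))
}

#' Area-level direct estimates ready for smoothing
#'
#' Convenience composition of [ht_ratio()], [design_variance()] and
#' [log_transform()] over a household table; counties absent from the data
#' are appended with a missing flag when `n_counties` is given (the
#' "no data for this county" case).
#'
#' @inheritParams ht_ratio
#' @param n_counties total number of counties in the map.
#' @return `AreaEstimate` tibble: `county_id`, `mu_hat`, `var_hat`,
#'   `theta_hat`, `V`, `n_households`, `missing`.
#' @export
area_estimates <- function(households, n_counties = NULL) {
  est <- design_variance(households)
  lt <- log_transform(est$mu_hat, est$var_hat)
  est <- dplyr::bind_cols(est, lt) |>
    dplyr::mutate(missing = FALSE)
  if (!is.null(n_counties)) {
    absent <- setdiff(seq_len(n_counties), est$county_id)
    if (length(absent))
      est <- dplyr::bind_rows(est, tibble(
        county_id = absent, mu_hat = NA_real_, var_hat = NA_real_,
        theta_hat = NA_real_, V = NA_real_, n_households = 0L,
        unstable = TRUE, missing = TRUE))
  }
  dplyr::arrange(est, .data$county_id)
}

#' Spatially smooth county density estimates
#'
#' Treats the log-scale direct estimates as Gaussian observations with
#' known variance `V_c` and fits
#' `theta_hat_c = beta0 + e_c + S_c` with iid county effects `e_c` and an
#' ICAR spatial effect `S_c` (sum-to-zero constrained), PC priors on both
#' standard deviations. The two hyperparameters are sampled by
#' random-walk Metropolis under the exact Gaussian marginal likelihood;
#' the latent field is drawn exactly per hyperparameter draw. Counties
#' without data (or without a finite log estimate) are predicted from
#' `beta0 + S_c`.
#'
#' @param estimates `AreaEstimate` tibble from [area_estimates()]; rows
#'   with `missing = TRUE` or non-finite `theta_hat`/`V` are smoothed over.
#' @param adjacency symmetric county adjacency matrix.
#' @param priors list with `eps` and `s`, PC priors on the two standard
#'   deviations (defaults `P(sigma > 1) = 0.01` each).
#' @param iter,warmup,seed Metropolis settings.
#' @param intercept_sd prior standard deviation of `beta0`.
#' @return `SmoothedArea` tibble of class `herd_smoothed`: `county_id`,
#'   `median` (posterior median of `exp(theta_c)`), `se` (posterior SD of
#'   `exp(theta_c)`), `theta_median`, `missing`; attributes carry
#'   hyperparameter draws and the effect decomposition posterior means.
#' @export
smooth_areas <- function(estimates, adjacency,
                         priors = list(eps = pc_sd(1, 0.01), s = pc_sd(1, 0.01)),
                         iter = 1200L, warmup = 400L, seed = 1L,
                         intercept_sd = sqrt(1000)) {
  est <- dplyr::arrange(as_tibble(estimates), .data$county_id)
  nc <- nrow(est)
  icar <- icar_precision(adjacency)
  if (nrow(icar$Q) != nc) abort("adjacency dimension does not match estimates")
  obs <- which(!est$missing & is.finite(est$theta_hat) & is.finite(est$V) &
                 !is.na(est$V))
  if (!length(obs)) abort("no usable direct estimates to smooth")
  th <- est$theta_hat[obs]
  V <- pmax(est$V[obs], 1e-10)
  kc <- 1e6

  # latent x = (beta0, eps[1..nc], S[1..nc]); design rows pick county terms
  M <- cbind(1, Diagonal(nc)[obs, , drop = FALSE],
             Diagonal(nc)[obs, , drop = FALSE])
  D <- Diagonal(length(obs), x = 1 / V)
  MtD <- crossprod(M, D)
  MtDM <- forceSymmetric(MtD %*% M)
  b <- as.numeric(MtD %*% th)
  qf_obs <- sum(th^2 / V)
  ll_const <- -0.5 * sum(log(2 * pi * V))
  R_icar <- icar$Q
  eigR <- eigen(as.matrix(R_icar), symmetric = TRUE, only.values = TRUE)$values
  ld_icar_pos <- sum(log(eigR[eigR > max(eigR) * 1e-9]))

  evidence <- function(z) {
    se <- exp(z[1]); ss <- exp(z[2])
    Qp <- Matrix::bdiag(Diagonal(1, x = 1 / intercept_sd^2),
                        Diagonal(nc, x = 1 / se^2),
                        R_icar / ss^2 + kc * tcrossprod(icar$null))
    ld_p <- -2 * log(intercept_sd) - 2 * nc * log(se) +
      ld_icar_pos - 2 * (nc - 1) * log(ss) + log(kc)
    Qpost <- forceSymmetric(Qp + MtDM)
    ch <- Matrix::Cholesky(Qpost, LDL = FALSE, perm = TRUE)
    xs <- as.numeric(solve(ch, b, system = "A"))
    ld_post <- as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                              sqrt = FALSE)$modulus)
    le <- ll_const - 0.5 * (qf_obs - sum(b * xs)) + 0.5 * ld_p - 0.5 * ld_post
    lp <- le + priors$eps$logpdf(se) + z[1] + priors$s$logpdf(ss) + z[2]
    list(lp = lp, ch = ch, xs = xs)
  }

  set.seed(seed)
  z <- log(c(0.5, 0.5))
  cur <- evidence(z)
  keep <- iter - warmup
  hdraw <- matrix(NA_real_, keep, 2L)
  theta_draws <- matrix(NA_real_, keep, nc)
  b0_draws <- numeric(keep)
  eps_sum <- numeric(nc); S_sum <- numeric(nc)
  g_scale <- 1
  d_lat <- 1L + 2L * nc
  for (it in seq_len(iter)) {
    prop <- z + g_scale * 0.35 * rnorm(2L)
    cand <- evidence(prop)
    a <- if (is.finite(cand$lp)) min(1, exp(cand$lp - cur$lp)) else 0
    if (runif(1) < a) { z <- prop; cur <- cand }
    if (it <= warmup) {
      g_scale <- exp(log(g_scale) + (a - 0.3) / it^0.6)
    } else {
      zz <- rnorm(d_lat)
      xdev <- as.numeric(solve(cur$ch, solve(cur$ch, zz, system = "Lt"),
                               system = "Pt"))
      x <- cur$xs + xdev
      beta0 <- x[1]; epsv <- x[1 + seq_len(nc)]; Sv <- x[1 + nc + seq_len(nc)]
      thc <- beta0 + epsv + Sv
      # counties without data: prediction from beta0 + S only
      nodata <- setdiff(seq_len(nc), obs)
      thc[nodata] <- beta0 + Sv[nodata]
      theta_draws[it - warmup, ] <- thc
      hdraw[it - warmup, ] <- exp(z)
      b0_draws[it - warmup] <- beta0
      eps_sum <- eps_sum + epsv; S_sum <- S_sum + Sv
    }
  }
  dens <- exp(theta_draws)
  out <- tibble(county_id = est$county_id,
                median = apply(dens, 2L, median),
                se = apply(dens, 2L, sd),
                theta_median = apply(theta_draws, 2L, median),
                missing = !seq_len(nc) %in% obs)
  structure(out,
            hyper = tibble(sigma_eps = hdraw[, 1], sigma_s = hdraw[, 2]),
            decomposition = list(beta0 = mean(b0_draws),
                                 eps_mean = eps_sum / keep,
                                 S_mean = S_sum / keep),
            class = c("herd_smoothed", class(tibble())))
}

#' Write smoothed county estimates with their geometry
#'
#' CSV of the estimates plus a GeoJSON FeatureCollection of county centers
#' (the synthetic counties are bbox cells; centers identify them).
#'
#' @param smoothed `herd_smoothed` tibble.
#' @param centers tibble `county_id`/`area_id`, `lon`, `lat`.
#' @param path_csv,path_geojson output paths.
#' @export
write_area_estimates <- function(smoothed, centers, path_csv, path_geojson) {
  readr::write_csv(as_tibble(smoothed), path_csv)
  ctr <- as_tibble(centers)
  idcol <- intersect(c("county_id", "area_id"), names(ctr))[1]
  feats <- lapply(seq_len(nrow(ctr)), function(i) {
    row <- smoothed[smoothed$county_id == ctr[[idcol]][i], ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(ctr$lon[i], ctr$lat[i])),
         properties = list(county_id = ctr[[idcol]][i],
                           median = if (nrow(row)) row$median else NA,
                           se = if (nrow(row)) row$se else NA))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path_geojson, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(path_csv, path_geojson))
}
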