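#' Zero-inflated Poisson (type 1) log-likelihood
#'
#' Mixture of structural zeros (probability `p`) and Poisson counts:
#' `Prob(Y | mu, p) = p 1[y = 0] + (1 - p) Poisson(y | mu)`.
#' Evaluated stably on the log scale for rates up to about 1e6.
#'
#' @param y non-negative integer counts (vectorized).
#' @param mu positive Poisson means.
#' @param p structural-zero probability in \[0, 1\] (scalar or vector).
#' @return numeric vector of log-likelihood contributions.
#' @export
zip_loglik <- function(y, mu, p) {
  if (any(y < 0) || any(y != round(y))) abort("y must be non-negative integers")
  if (any(mu <= 0)) abort("mu must be > 0")
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  n <- max(length(y), length(mu), length(p))
  y <- rep_len(y, n); mu <- rep_len(mu, n); p <- rep_len(p, n)
  out <- numeric(n)
  z <- y == 0
  # log(p + (1-p) exp(-mu)) computed via log-sum-exp for stability
  if (any(z)) {
    lp <- log(p[z]); l1p <- log1p(-p[z])
    a <- lp; b <- l1p - mu[z]
    m <- pmax(a, b)
    m[!is.finite(m)] <- 0
    out[z] <- ifelse(p[z] == 0, -mu[z],
                     ifelse(p[z] == 1, 0, m + log(exp(a - m) + exp(b - m))))
  }
  if (any(!z)) {
    out[!z] <- ifelse(p[!z] == 1, -Inf,
                      log1p(-p[!z]) + dpois(y[!z], mu[!z], log = TRUE))
  }
  out
}

# gradient and (clipped) negative curvature of the ZIP log-likelihood in the
# log-rate eta = log(mu); used by the sparse Newton solver
zip_eta_derivs <- function(y, eta, p) {
  mu <- exp(pmin(eta, 30))
  g <- y - mu
  c_ <- mu
  z <- y == 0
  if (any(z) && p > 0) {
    muz <- mu[z]
    # w = (1-p) e^{-mu} / (p + (1-p) e^{-mu}), computed stably
    lw <- log1p(-p) - muz - log(p + (1 - p) * exp(-pmin(muz, 700)))
    w <- exp(pmin(lw, 0))
    g[z] <- -w * muz
    c_[z] <- muz * w * (1 - muz * (1 - w))
  }
  list(grad = g, curv = pmax(c_, 1e-8))
}

zip_ll_eta <- function(y, eta, p) {
  sum(zip_loglik(y, exp(pmin(eta, 30)), p))
}

#' Specify a candidate model from the six-model menu
#'
#' The menu varies the fixed effects and the flexibility of the temporal
#' random effect while keeping the random-effect structure fixed:
#' model 1 intercept only; model 2 adds urban/rural; model 3 adds protected
#' areas; model 4 adds bodies of water; model 5 adds elevation; model 6 has
#' all of model 5's covariates but a random walk of order 1 in time instead
#' of order 2. The restricted variant (used where data are sparse) drops the
#' space-time interaction and the unstructured survey and year effects,
#' keeping the spatial field, the temporal random walk, and the cluster
#' nugget.
#'
#' @param model integer 1-6, or `"drc_restricted"` (model 2 with the
#'   restriction applied).
#' @param species `"cattle"` or `"pig"`; label only, selects which count
#'   column is modeled by the readers.
#' @param restricted logical; apply the restricted random-effect set.
#' @return object of class `herd_model_spec`.
#' @export
model_spec <- function(model = 5, species = c("cattle", "pig"),
                       restricted = FALSE) {
  species <- match.arg(species)
  if (identical(model, "drc_restricted")) {
    model <- 2L
    restricted <- TRUE
  }
  model <- as.integer(model)
  if (!model %in% 1:6) abort("model must be 1-6 or \"drc_restricted\"")
  fx_all <- c("urban", "protected", "water", "elevation")
  fixed <- c("intercept", fx_all[seq_len(min(model - 1L, 4L))])
  if (model == 6L) fixed <- c("intercept", fx_all)
  effects <- list(spde = TRUE, rw = TRUE, iid_cluster = TRUE,
                  iid_survey = !restricted, iid_year = !restricted,
                  spacetime = !restricted)
  structure(list(model = model, species = species, restricted = restricted,
                 fixed_effects = fixed,
                 temporal_order = if (model == 6L) 1L else 2L,
                 effects = effects),
            class = "herd_model_spec")
}

#' @export
print.herd_model_spec <- function(x, ...) {
  cat("<herd_model_spec> model ", x$model,
      if (x$restricted) " (restricted)", " [", x$species, "]\n", sep = "")
  cat("  fixed: ", paste(x$fixed_effects, collapse = ", "), "\n", sep = "")
  cat("  temporal: rw", x$temporal_order, "; effects: ",
      paste(names(x$effects)[unlist(x$effects)], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of non-intercept fixed effects (for tie-breaking in selection)
#' @keywords internal
n_fixed_effects <- function(spec) length(spec$fixed_effects) - 1L

#' Cluster-level Poisson rates from a latent state
#'
#' Evaluates `mu_i = exp(alpha0 + x_i' beta + S(s_i) + omega_t + eps_i +
#' gamma_k + eta_t + u(s_i, t) + log D_i)`, including exactly the terms the
#' model spec enables. Disabled terms are dropped; `state` entries for
#' disabled effects are ignored.
#'
#' @param spec a `herd_model_spec`.
#' @param data cluster tibble with columns `lon`, `lat`, `year`,
#'   `survey_id`, `human_count` and the covariates named by the spec.
#' @param state named list: `alpha0`, `beta` (named by covariate), `S`
#'   (mesh-vertex values), `omega` (per year), `eps` (per cluster), `gamma`
#'   (per survey), `eta` (per year), `u` (n_vertices x T matrix), plus
#'   `mesh` / `A` for projection and `years` giving the year axis.
#' @return numeric vector of rates `mu` (strictly positive).
#' @export
linear_predictor <- function(spec, data, state) {
  n <- nrow(data)
  if (any(data$human_count < 1)) abort("human_count must be >= 1 for every cluster")
  eta <- rep(state$alpha0 %||% 0, n) + log(data$human_count)
  for (v in setdiff(spec$fixed_effects, "intercept")) {
    if (!v %in% names(data)) abort(paste0("missing covariate '", v, "' in data"))
    if (anyNA(data[[v]])) {
      bad <- which(is.na(data[[v]]))[1]
      abort(paste0("missing value of covariate '", v, "' at cluster row ", bad))
    }
    b <- state$beta[[v]] %||% 0
    eta <- eta + b * data[[v]]
  }
  A <- state$A
  if (is.null(A) && !is.null(state$mesh)) A <- project_points(state$mesh, cbind(data$lon, data$lat))
  yrs <- state$years
  t_i <- if (!is.null(yrs)) match(data$year, yrs) else rep(1L, n)
  if (isTRUE(spec$effects$spde) && !is.null(state$S)) eta <- eta + as.numeric(A %*% state$S)
  if (isTRUE(spec$effects$rw) && !is.null(state$omega)) eta <- eta + state$omega[t_i]
  if (isTRUE(spec$effects$iid_cluster) && !is.null(state$eps)) eta <- eta + state$eps
  if (isTRUE(spec$effects$iid_survey) && !is.null(state$gamma)) {
    k_i <- match(data$survey_id, sort(unique(data$survey_id)))
    eta <- eta + state$gamma[k_i]
  }
  if (isTRUE(spec$effects$iid_year) && !is.null(state$eta_t)) eta <- eta + state$eta_t[t_i]
  if (isTRUE(spec$effects$spacetime) && !is.null(state$u)) {
    ut <- vapply(seq_len(n), function(i) sum(A[i, ] * state$u[, t_i[i]]), numeric(1))
    eta <- eta + ut
  }
  exp(eta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
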