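#' Default prior set for the density model
#'
#' PC priors calibrated as: spatial range `P(rho_s < 0.3) = 0.05`, spatial
#' and space-time standard deviation `P(sigma > 1) = 0.05`, AR(1)
#' correlation `P(rho_t > 0.5) = 0.8` (base model `cor1`), iid random-effect
#' scales `P(sigma^2 > 0.5) = 0.01`, a Gamma(1, 5e-5) prior on the
#' random-walk precision, a logit-normal prior on the structural-zero
#' probability, and a diffuse Normal(0, 31.6^2) on fixed effects.
#'
#' @param ar1_base base model for the AR(1) PC prior.
#' @return named list of prior objects, the shape [fit_zip_model()] expects.
#' @export
default_priors <- function(ar1_base = "cor1") {
  list(matern = pc_matern(0.3, 0.05, 1, 0.05),
       sigma_st = pc_sd(1, 0.05),
       rw = prior_gamma_precision(1, 5e-5),
       iid = pc_sd_from_variance_bound(0.5, 0.01),
       ar1 = pc_ar1(0.5, 0.8, ar1_base),
       p_logit = c(mean = -1, sd = 1),
       fixed_sd = sqrt(1000))
}

#' Inference settings
#'
#' @param method `"mcmc"` (Laplace-within-Metropolis over hyperparameters,
#'   the default) or `"map"` (posterior mode of the hyperparameters with a
#'   Gaussian approximation for the latent field; fast path used in
#'   cross-validation loops).
#' @param iter total Metropolis iterations (including warmup).
#' @param warmup adaptation iterations discarded from the chain.
#' @param seed RNG seed; every stochastic step of the fit flows from it.
#' @param fix_p fix the structural-zero probability (0 collapses the
#'   likelihood to Poisson); `NULL` estimates it.
#' @param constraint_precision precision of the soft sum-to-zero
#'   constraints on rank-deficient temporal effects.
#' @param init optional named list overriding initial hyperparameter values
#'   (natural scale).
#' @param verbose print progress.
#' @export
fit_control <- function(method = c("mcmc", "map"), iter = 600L, warmup = 200L,
                        seed = 1L, fix_p = NULL, constraint_precision = 1e6,
                        init = list(), map_maxit = 400L, map_reltol = 1e-6,
                        verbose = FALSE) {
  method <- match.arg(method)
  if (iter <= warmup && method == "mcmc") abort("iter must exceed warmup")
  list(method = method, iter = as.integer(iter), warmup = as.integer(warmup),
       seed = as.integer(seed), fix_p = fix_p,
       constraint_precision = constraint_precision, init = init,
       map_maxit = as.integer(map_maxit), map_reltol = map_reltol,
       verbose = isTRUE(verbose))
}

# ---- model data assembly ----------------------------------------------------

build_model_data <- function(spec, data, mesh, priors, control) {
  stopifnot(inherits(spec, "herd_model_spec"))
  data <- as_tibble(data)
  need <- c("lon", "lat", "year", "survey_id", "human_count", "livestock_count")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("data lacks columns: ", paste(miss, collapse = ", ")))
  if (any(data$human_count < 1)) abort("human_count must be >= 1")
  y <- data$livestock_count
  if (anyNA(y)) abort("livestock_count has missing values; filter with read_cluster_table()")

  eff <- spec$effects
  years <- seq(min(data$year), max(data$year))
  T_ <- length(years)
  temporal <- eff$rw || eff$iid_year || eff$spacetime
  if (temporal && length(unique(data$year)) < 2L)
    abort("temporal effects enabled but data span fewer than 2 years")
  t_i <- match(data$year, years)
  surveys <- sort(unique(data$survey_id))
  k_i <- match(data$survey_id, surveys)
  n <- nrow(data)

  covs <- setdiff(spec$fixed_effects, "intercept")
  X <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  scaling <- list()
  for (v in covs) {
    if (!v %in% names(data)) abort(paste0("missing covariate '", v, "'"))
    if (anyNA(data[[v]])) {
      bad <- which(is.na(data[[v]]))[1]
      abort(paste0("missing covariate '", v, "' at cluster row ", bad))
    }
    col <- as.numeric(data[[v]])
    if (v == "elevation") {
      scaling[[v]] <- c(center = mean(col), scale = max(sd(col), 1e-9))
      col <- (col - scaling[[v]]["center"]) / scaling[[v]]["scale"]
    }
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- v
  }

  fem <- fem_matrices(mesh)
  parts <- spde_parts(fem)
  nv <- fem$n
  A_s <- project_points(mesh, cbind(data$lon, data$lat))

  blocks <- tibble(block = "fixed", size = ncol(X))
  design <- list(Matrix::Matrix(X, sparse = TRUE))
  if (eff$spde) {
    blocks <- dplyr::bind_rows(blocks, tibble(block = "spde", size = nv))
    design <- c(design, list(A_s))
  }
  Z_year <- sparseMatrix(i = seq_len(n), j = t_i, x = 1, dims = c(n, T_))
  if (eff$rw) {
    blocks <- dplyr::bind_rows(blocks, tibble(block = "rw", size = T_))
    design <- c(design, list(Z_year))
  }
  if (eff$iid_cluster) {
    blocks <- dplyr::bind_rows(blocks, tibble(block = "eps", size = n))
    design <- c(design, list(Diagonal(n)))
  }
  if (eff$iid_survey) {
    blocks <- dplyr::bind_rows(blocks, tibble(block = "gamma", size = length(surveys)))
    design <- c(design, list(sparseMatrix(i = seq_len(n), j = k_i, x = 1,
                                          dims = c(n, length(surveys)))))
  }
  if (eff$iid_year) {
    blocks <- dplyr::bind_rows(blocks, tibble(block = "eta", size = T_))
    design <- c(design, list(Z_year))
  }
  if (eff$spacetime) {
    blocks <- dplyr::bind_rows(blocks, tibble(block = "st", size = nv * T_))
    Ast <- sparseMatrix(i = rep(seq_len(n), each = 0L), j = integer(0), x = numeric(0),
                        dims = c(n, nv * T_))
    tr <- Matrix::mat2triplet(A_s)
    Ast <- sparseMatrix(i = tr$i, j = tr$j + (t_i[tr$i] - 1L) * nv, x = tr$x,
                        dims = c(n, nv * T_))
    design <- c(design, list(Ast))
  }
  blocks$start <- cumsum(c(1L, head(blocks$size, -1L)))
  M <- do.call(cbind, design)

  rw_str <- if (eff$rw) rw_precision(T_, spec$temporal_order) else NULL
  rw_eig <- if (eff$rw) {
    ev <- eigen(as.matrix(rw_str$R), symmetric = TRUE, only.values = TRUE)$values
    sum(log(ev[ev > max(ev) * 1e-9]))
  } else NULL

  hyper <- character(0)
  if (eff$spde || eff$spacetime) hyper <- c(hyper, "rho_s")
  if (eff$spde) hyper <- c(hyper, "sigma_s")
  if (eff$rw) hyper <- c(hyper, "sigma_rw")
  if (eff$iid_cluster) hyper <- c(hyper, "sigma_eps")
  if (eff$iid_survey) hyper <- c(hyper, "sigma_gamma")
  if (eff$iid_year) hyper <- c(hyper, "sigma_eta")
  if (eff$spacetime) hyper <- c(hyper, "sigma_st", "rho_t")
  if (is.null(control$fix_p)) hyper <- c(hyper, "p")

  list(cache = new.env(parent = emptyenv()),
       spec = spec, data = data, y = y, offset = log(data$human_count),
       M = M, blocks = blocks, n = n, X = X, scaling = scaling,
       years = years, T = T_, surveys = surveys, t_i = t_i, k_i = k_i,
       mesh = mesh, fem = fem, parts = parts, nv = nv, A_s = A_s,
       rw_str = rw_str, rw_eig = rw_eig, hyper = hyper,
       priors = priors, kc = control$constraint_precision,
       fix_p = control$fix_p, fixed_prec = 1 / priors$fixed_sd^2)
}

# natural <-> unconstrained transforms for the hyperparameter vector
hyper_transform <- function(name) {
  if (name %in% c("rho_s", "sigma_s", "sigma_rw", "sigma_eps", "sigma_gamma",
                  "sigma_eta", "sigma_st")) "log"
  else if (name == "rho_t") "logit2"
  else if (name == "p") "logit"
  else abort(paste0("unknown hyperparameter ", name))
}

hyper_to_natural <- function(z, names) {
  out <- numeric(length(z))
  for (i in seq_along(z)) {
    out[i] <- switch(hyper_transform(names[i]),
                     log = exp(z[i]),
                     logit2 = 2 * stats::plogis(z[i]) - 1,
                     logit = stats::plogis(z[i]))
  }
  setNames(out, names)
}

hyper_to_z <- function(nat, names) {
  out <- numeric(length(nat))
  for (i in seq_along(nat)) {
    out[i] <- switch(hyper_transform(names[i]),
                     log = log(nat[i]),
                     logit2 = stats::qlogis((nat[i] + 1) / 2),
                     logit = stats::qlogis(nat[i]))
  }
  setNames(out, names)
}

# log prior density of the transformed hyperparameter vector (includes
# Jacobians of the transforms)
hyper_logprior <- function(z, md) {
  nm <- md$hyper
  th <- hyper_to_natural(z, nm)
  pr <- md$priors
  lp <- 0
  if ("rho_s" %in% nm && "sigma_s" %in% nm) {
    lp <- lp + pr$matern$logpdf(th["rho_s"], th["sigma_s"]) +
      z[match("rho_s", nm)] + z[match("sigma_s", nm)]
  } else if ("rho_s" %in% nm) {
    lp <- lp + pr$matern$logpdf_rho(th["rho_s"]) + z[match("rho_s", nm)]
  }
  for (s in intersect(c("sigma_eps", "sigma_gamma", "sigma_eta"), nm))
    lp <- lp + pr$iid$logpdf(th[s]) + z[match(s, nm)]
  if ("sigma_rw" %in% nm)
    lp <- lp + pr$rw$logpdf(th["sigma_rw"]) + z[match("sigma_rw", nm)]
  if ("sigma_st" %in% nm)
    lp <- lp + pr$sigma_st$logpdf(th["sigma_st"]) + z[match("sigma_st", nm)]
  if ("rho_t" %in% nm) {
    zz <- z[match("rho_t", nm)]
    s <- stats::plogis(zz)
    lp <- lp + pr$ar1$logpdf(th["rho_t"]) + log(2) + log(s) + log1p(-s)
  }
  if ("p" %in% nm) {
    zz <- z[match("p", nm)]
    lp <- lp + stats::dnorm(zz, pr$p_logit["mean"], pr$p_logit["sd"], log = TRUE)
  }
  as.numeric(lp)
}

# assemble the prior precision over the latent vector and its exact
# generalized log-determinant
assemble_prior <- function(md, th) {
  kc <- md$kc
  Qs <- NULL; ld <- 0
  qlist <- list()
  for (b in seq_len(nrow(md$blocks))) {
    nm <- md$blocks$block[b]; sz <- md$blocks$size[b]
    if (nm == "fixed") {
      qlist[[b]] <- Diagonal(sz, x = md$fixed_prec)
      ld <- ld + sz * log(md$fixed_prec)
    } else if (nm == "spde") {
      Qs1 <- spde_assemble(md$parts, th["rho_s"], 1)
      ld0 <- chol_logdet(Qs1)
      qlist[[b]] <- Qs1 / th["sigma_s"]^2
      ld <- ld + ld0 - 2 * sz * log(th["sigma_s"])
      attr(qlist, "Qs1") <- Qs1
      attr(qlist, "ld0") <- ld0
    } else if (nm == "rw") {
      U <- md$rw_str$null
      qlist[[b]] <- md$rw_str$R / th["sigma_rw"]^2 + kc * tcrossprod(U)
      ord <- md$rw_str$order
      ld <- ld + md$rw_eig - 2 * (sz - ord) * log(th["sigma_rw"]) + ord * log(kc)
    } else if (nm == "eps") {
      qlist[[b]] <- Diagonal(sz, x = 1 / th["sigma_eps"]^2)
      ld <- ld - 2 * sz * log(th["sigma_eps"])
    } else if (nm == "gamma") {
      qlist[[b]] <- Diagonal(sz, x = 1 / th["sigma_gamma"]^2)
      ld <- ld - 2 * sz * log(th["sigma_gamma"])
    } else if (nm == "eta") {
      qlist[[b]] <- Diagonal(sz, x = 1 / th["sigma_eta"]^2) +
        Matrix::Matrix(kc / sz, sz, sz)
      ld <- ld - 2 * (sz - 1) * log(th["sigma_eta"]) +
        log(1 / th["sigma_eta"]^2 + kc)
    } else if (nm == "st") {
      Qs1 <- attr(qlist, "Qs1")
      if (is.null(Qs1)) {
        Qs1 <- spde_assemble(md$parts, th["rho_s"], 1)
        attr(qlist, "ld0") <- chol_logdet(Qs1)
      }
      Qa <- ar1_precision(md$T, th["rho_t"])
      qlist[[b]] <- (Qa %x% Qs1) / th["sigma_st"]^2
      ld <- ld + md$nv * (-(md$T - 1) * log(1 - th["rho_t"]^2)) +
        md$T * (attr(qlist, "ld0") - 2 * md$nv * log(th["sigma_st"]))
    }
  }
  Q <- forceSymmetric(Matrix::bdiag(qlist))
  list(Q = Q, logdet = ld)
}

chol_logdet <- function(Q) {
  ch <- Matrix::Cholesky(forceSymmetric(Q), LDL = FALSE, perm = TRUE)
  as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
}

# Posterior precision Q_prior + M' W M assembled by updating the value slot
# of a cached pattern template: the sparsity pattern is fixed for a given
# model structure, so after the first call no S4 sparse arithmetic is needed
# in the Newton loop. K maps per-observation curvatures to the template
# entries of the M'WM part; qmap places the prior entries.
qpost_build <- function(md, Qp, curv) {
  cache <- md$cache
  if (is.null(cache$tmpl)) {
    M <- md$M
    DM <- Diagonal(md$n, x = sqrt(curv)) %*% M
    Qpc <- as(forceSymmetric(Qp), "CsparseMatrix")
    tmpl <- as(Qpc + crossprod(DM), "CsparseMatrix")
    N <- nrow(tmpl)
    key_of <- function(A) {
      # keys of the stored (upper) entries of a dsCMatrix
      ii <- A@i + 1L
      jj <- rep.int(seq_len(N), diff(A@p))
      ii + (jj - 1) * as.double(N)
    }
    keyT <- key_of(tmpl)
    qkeys <- key_of(Qpc)
    cache$qmap <- match(qkeys, keyT)
    cache$qp_len <- length(qkeys)
    tr <- Matrix::mat2triplet(M)
    ord <- order(tr$i)
    ti <- tr$i[ord]; tj <- tr$j[ord]; tx <- tr$x[ord]
    rows <- split(seq_along(ti), ti)
    pair_lut <- list()
    parts_i <- parts_j <- parts_x <- vector("list", length(rows))
    for (rr in seq_along(rows)) {
      idx <- rows[[rr]]
      m <- length(idx)
      lut <- pair_lut[[as.character(m)]]
      if (is.null(lut)) {
        lut <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
        pair_lut[[as.character(m)]] <- lut
      }
      cols <- tj[idx]; vals <- tx[idx]
      ca <- cols[lut[, 1]]; cb <- cols[lut[, 2]]
      parts_i[[rr]] <- pmin(ca, cb) + (pmax(ca, cb) - 1) * as.double(N)
      parts_j[[rr]] <- rep.int(ti[idx][1], nrow(lut))
      parts_x[[rr]] <- vals[lut[, 1]] * vals[lut[, 2]]
    }
    pos <- match(unlist(parts_i), keyT)
    cache$K <- sparseMatrix(i = pos, j = unlist(parts_j),
                            x = unlist(parts_x),
                            dims = c(length(keyT), md$n))
    cache$tmpl <- tmpl
    cache$nnzT <- length(keyT)
    return(tmpl)
  }
  qx <- as(Qp, "CsparseMatrix")@x
  if (length(qx) != cache$qp_len) {  # pattern drifted: rebuild the template
    cache$tmpl <- NULL
    return(qpost_build(md, Qp, curv))
  }
  xnew <- numeric(cache$nnzT)
  xnew[cache$qmap] <- qx
  xnew <- xnew + as.numeric(cache$K %*% curv)
  out <- cache$tmpl
  out@x <- xnew
  out
}

# Cholesky with reuse of the symbolic analysis: the posterior precision
# pattern is fixed for a given model structure, so only the numeric factor
# needs updating after the first call
chol_cached <- function(md, Qpost) {
  Qc <- as(Qpost, "CsparseMatrix")
  if (is.null(md$cache$sym)) {
    ch <- Matrix::Cholesky(Qc, LDL = FALSE, perm = TRUE)
    md$cache$sym <- ch
    return(ch)
  }
  tryCatch(Matrix::.updateCHMfactor(md$cache$sym, Qc, mult = 0),
           error = function(e) {
             ch <- Matrix::Cholesky(Qc, LDL = FALSE, perm = TRUE)
             md$cache$sym <- ch
             ch
           })
}

# sparse Newton ascent to the joint mode of latent field given
# hyperparameters; returns mode, log-evidence pieces, final factorization
laplace_fit <- function(md, Qp_obj, p, x0 = NULL) {
  Qp <- Qp_obj$Q
  M <- md$M; y <- md$y; off <- md$offset
  d <- ncol(M)
  x <- if (is.null(x0)) numeric(d) else x0
  eta <- as.numeric(off + M %*% x)
  obj <- zip_ll_eta(y, eta, p) - 0.5 * sum(x * as.numeric(Qp %*% x))
  ch <- NULL
  for (it in seq_len(60L)) {
    dv <- zip_eta_derivs(y, eta, p)
    Qpost <- qpost_build(md, Qp, dv$curv)
    ch <- chol_cached(md, Qpost)
    b <- as.numeric(crossprod(M, dv$grad)) - as.numeric(Qp %*% x)
    dx <- as.numeric(solve(ch, b, system = "A"))
    step <- 1
    repeat {
      xn <- x + step * dx
      etan <- as.numeric(off + M %*% xn)
      objn <- zip_ll_eta(y, etan, p) - 0.5 * sum(xn * as.numeric(Qp %*% xn))
      if (is.finite(objn) && objn >= obj - 1e-12) break
      step <- step / 2
      if (step < 1e-8) { xn <- x; etan <- eta; objn <- obj; break }
    }
    improved <- objn - obj
    x <- xn; eta <- etan; obj <- objn
    # at convergence the step is negligible, so the factor from this
    # iteration is the curvature at the mode to working accuracy
    if (improved < 1e-7) break
  }
  if (is.null(ch)) {
    dv <- zip_eta_derivs(y, eta, p)
    ch <- chol_cached(md, qpost_build(md, Qp, dv$curv))
  }
  ld_post <- as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
  evidence <- obj + 0.5 * Qp_obj$logdet - 0.5 * ld_post
  list(x = x, eta = eta, obj = obj, chol = ch, evidence = evidence,
       logdet_post = ld_post)
}

log_posterior_theta <- function(z, md, state_env = NULL) {
  th <- hyper_to_natural(z, md$hyper)
  p <- if (is.null(md$fix_p)) th[["p"]] else md$fix_p
  Qp <- assemble_prior(md, th)
  x0 <- if (!is.null(state_env)) state_env$x0 else NULL
  lf <- laplace_fit(md, Qp, p, x0 = x0)
  if (!is.null(state_env)) state_env$x0 <- lf$x
  lf$evidence + hyper_logprior(z, md)
}

#' Fit the zero-inflated Poisson density model
#'
#' Assembles the hierarchical model named by `spec` -- fixed effects, the
#' SPDE spatial field, temporal random walk, unstructured cluster / survey /
#' year effects, separable space-time interaction, a human-count offset and
#' a shared structural-zero probability -- and produces an approximate
#' posterior. Conditional on hyperparameters the latent field posterior is
#' approximated by a Gaussian at its mode (sparse Newton / Laplace
#' approximation); the marginal posterior of the hyperparameters is then
#' explored by adaptive random-walk Metropolis under the Laplace-approximated
#' evidence, or maximized (`method = "map"`) for a fast point fit.
#'
#' @param data cluster tibble (see [simulate_survey()] / [read_cluster_table()]).
#' @param mesh a `herd_mesh` covering all cluster locations.
#' @param spec a `herd_model_spec`.
#' @param priors prior list from [default_priors()].
#' @param control settings from [fit_control()].
#' @return object of class `herd_fit` with the hyperparameter chain
#'   (natural scale), acceptance diagnostics and everything needed by
#'   [posterior_sample()].
#' @export
fit_zip_model <- function(data, mesh, spec = model_spec(2), priors = default_priors(),
                          control = fit_control()) {
  md <- build_model_data(spec, data, mesh, priors, control)
  set.seed(control$seed)
  init <- list(rho_s = priors$matern$rho0 * 1.5, sigma_s = 0.5, sigma_rw = 0.3,
               sigma_eps = 0.3, sigma_gamma = 0.3, sigma_eta = 0.2,
               sigma_st = 0.3, rho_t = 0.7,
               p = min(0.5, max(0.02, mean(md$y == 0) / 2)))
  init <- modifyList(init, control$init)
  z <- hyper_to_z(unlist(init[md$hyper]), md$hyper)
  env <- new.env(); env$x0 <- NULL

  if (length(md$hyper) == 0L) {
    # no hyperparameters (e.g. fixed effects only with p fixed): the Laplace
    # approximation at the empty hyperparameter vector is the posterior
    lp <- log_posterior_theta(numeric(0), md, env)
    chain <- matrix(numeric(0), 1L, 0L)
    return(structure(list(md = md, chain_z = chain,
                          chain = as_tibble(as.data.frame(chain)),
                          logpost = lp,
                          diagnostics = list(accept_rate = NA_real_,
                                             ess = NA_real_, converged = TRUE),
                          control = control, seed = control$seed),
                     class = "herd_fit"))
  }

  if (control$method == "map") {
    opt <- optim(z, function(zz) -log_posterior_theta(zz, md, env),
                 method = "Nelder-Mead",
                 control = list(maxit = control$map_maxit,
                                reltol = control$map_reltol))
    chain <- matrix(opt$par, 1L, dimnames = list(NULL, md$hyper))
    lp <- -opt$value
    out_diag <- list(accept_rate = NA_real_, ess = NA_real_,
                     converged = opt$convergence == 0)
    if (opt$convergence != 0)
      warn("MAP optimization did not report convergence",
           class = "herd_convergence_warning")
    chain_nat <- matrix(hyper_to_natural(opt$par, md$hyper), 1L,
                        dimnames = list(NULL, md$hyper))
    lps <- lp
  } else {
    n_iter <- control$iter; n_warm <- control$warmup
    d <- length(z)
    # locate the hyperparameter posterior mode and measure its curvature;
    # random-walk proposals matched to the local covariance mix far better
    # than cold-start adaptation
    opt <- if (d == 1L) {
      o <- stats::optimize(function(zz) -log_posterior_theta(zz, md, env),
                           interval = c(z - 6, z + 6), tol = 1e-3)
      list(par = o$minimum, value = o$objective)
    } else {
      optim(z, function(zz) -log_posterior_theta(zz, md, env),
            method = "Nelder-Mead",
            control = list(maxit = control$map_maxit, reltol = 1e-6))
    }
    z <- opt$par
    H <- numeric_hessian(function(zz) log_posterior_theta(zz, md, env), z)
    Sig <- tryCatch(solve(-(H + t(H)) / 2), error = function(e) NULL)
    hess_ok <- !is.null(Sig) && all(is.finite(Sig)) &&
      all(eigen((Sig + t(Sig)) / 2, symmetric = TRUE,
                only.values = TRUE)$values > 0)
    prop_chol <- if (hess_ok) chol((2.38^2 / d) * (Sig + t(Sig)) / 2)
                 else diag(0.2, d)
    g_scale <- 1
    cur_lp <- log_posterior_theta(z, md, env)
    chain_z <- matrix(NA_real_, n_iter - n_warm, d)
    lps <- numeric(n_iter - n_warm)
    n_acc <- 0L
    for (it in seq_len(n_iter)) {
      prop <- z + g_scale * as.numeric(crossprod(prop_chol, rnorm(d)))
      prop_lp <- log_posterior_theta(prop, md, env)
      a <- if (is.finite(prop_lp)) min(1, exp(prop_lp - cur_lp)) else 0
      if (runif(1) < a) {
        z <- prop; cur_lp <- prop_lp
        if (it > n_warm) n_acc <- n_acc + 1L
      }
      if (it <= n_warm) {
        g_scale <- exp(log(g_scale) + (a - 0.3) / it^0.6)
      } else {
        chain_z[it - n_warm, ] <- z
        lps[it - n_warm] <- cur_lp
      }
      if (control$verbose && it %% 100 == 0)
        inform(sprintf("iter %d lp %.2f scale %.3f", it, cur_lp, g_scale))
    }
    acc <- n_acc / (n_iter - n_warm)
    chain_nat <- t(apply(chain_z, 1L, hyper_to_natural, names = md$hyper))
    if (d == 1L) chain_nat <- matrix(as.numeric(chain_nat), ncol = 1L)
    colnames(chain_nat) <- md$hyper
    ess <- apply(chain_z, 2L, ess_of)
    out_diag <- list(accept_rate = acc, ess = setNames(ess, md$hyper),
                     converged = acc > 0.03 && acc < 0.97 && min(ess) > 15)
    if (!out_diag$converged)
      warn(sprintf(paste0("possible non-convergence: acceptance rate %.2f, ",
                          "min ESS %.0f (%s)"), acc, min(ess),
                   md$hyper[which.min(ess)]),
           class = "herd_convergence_warning")
    chain <- chain_z
  }

  structure(list(md = md, chain_z = chain, chain = as_tibble(as.data.frame(chain_nat)),
                 logpost = lps, diagnostics = out_diag,
                 control = control, seed = control$seed),
            class = "herd_fit")
}

# central-difference Hessian; the target is smooth in the transformed
# hyperparameters and deterministic given them
numeric_hessian <- function(f, x, h = 0.03) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in (i + 1L):d) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

ess_of <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(ifelse(sd(x) == 0, 1, n))
  ac <- acf(x, lag.max = min(100L, n - 1L), plot = FALSE)$acf[-1]
  neg <- which(ac < 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1L)]
  n / (1 + 2 * sum(ac))
}

#' @export
print.herd_fit <- function(x, ...) {
  cat("<herd_fit> model ", x$md$spec$model,
      if (x$md$spec$restricted) " (restricted)", ", ", x$md$n, " clusters, ",
      x$md$T, " years, method ", x$control$method, "\n", sep = "")
  s <- tidy(x)
  print(s, n = nrow(s))
  invisible(x)
}

#' Posterior summaries of the hyperparameters
#'
#' @param x a `herd_fit`.
#' @param level credible-interval level.
#' @param ... unused.
#' @return tibble with `term`, `estimate` (posterior median), `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.herd_fit <- function(x, level = 0.95, ...) {
  ql <- (1 - level) / 2
  purrr::map_dfr(names(x$chain), function(nm) {
    v <- x$chain[[nm]]
    tibble(term = nm, estimate = median(v), std.error = sd(v),
           conf.low = unname(quantile(v, ql)),
           conf.high = unname(quantile(v, 1 - ql)))
  })
}

#' @export
glance.herd_fit <- function(x, ...) {
  tibble(n_obs = x$md$n, n_latent = ncol(x$md$M),
         n_hyper = length(x$md$hyper),
         n_draws = nrow(x$chain),
         accept_rate = x$diagnostics$accept_rate,
         min_ess = if (all(is.na(x$diagnostics$ess))) NA_real_
                   else min(x$diagnostics$ess),
         converged = x$diagnostics$converged,
         method = x$control$method)
}

#' Draw from the approximate posterior of the latent field
#'
#' For each retained hyperparameter draw, the latent field is sampled from
#' its Gaussian (Laplace) approximation at that hyperparameter value.
#' Prediction mode (`include_iid = FALSE`, the default) excludes the
#' unstructured cluster, survey and year effects, which are treated as
#' measurement error.
#'
#' @param fit a `herd_fit`.
#' @param n number of draws (default 1000).
#' @param seed RNG seed.
#' @param include_iid keep unstructured-effect draws.
#' @return object of class `herd_draws`: `latent` (n x d matrix), `blocks`
#'   (block index map), `hyper` (tibble of hyperparameter draws), `years`,
#'   `spec`, plus fixed-effect naming.
#' @export
posterior_sample <- function(fit, n = 1000L, seed = 1L, include_iid = FALSE) {
  if (n <= 0) abort("n must be positive")
  md <- fit$md
  set.seed(seed)
  R <- nrow(fit$chain_z)
  idx <- if (R >= n) round(seq(1L, R, length.out = n)) else sample.int(R, n, replace = TRUE)
  keyz <- apply(fit$chain_z[idx, , drop = FALSE], 1L, paste, collapse = ",")
  d <- ncol(md$M)
  lat <- matrix(NA_real_, n, d)
  env <- new.env(); env$x0 <- NULL
  for (k in unique(keyz)) {
    rows <- which(keyz == k)
    z <- fit$chain_z[idx[rows[1]], ]
    th <- hyper_to_natural(z, md$hyper)
    p <- if (is.null(md$fix_p)) th[["p"]] else md$fix_p
    Qp <- assemble_prior(md, th)
    lf <- laplace_fit(md, Qp, p, x0 = env$x0)
    env$x0 <- lf$x
    zmat <- matrix(rnorm(d * length(rows)), d, length(rows))
    y <- solve(lf$chol, zmat, system = "Lt")
    xs <- as.matrix(solve(lf$chol, y, system = "Pt"))
    lat[rows, ] <- t(xs + lf$x)
  }
  blocks <- md$blocks
  keep <- if (include_iid) blocks$block else setdiff(blocks$block, c("eps", "gamma", "eta"))
  cols <- unlist(lapply(keep, function(b) {
    r <- blocks[blocks$block == b, ]
    seq(r$start, r$start + r$size - 1L)
  }))
  newblocks <- blocks[blocks$block %in% keep, ]
  newblocks$start <- cumsum(c(1L, head(newblocks$size, -1L)))
  hyper <- fit$chain[idx, , drop = FALSE]
  structure(list(latent = lat[, cols, drop = FALSE], blocks = newblocks,
                 hyper = as_tibble(hyper), years = md$years,
                 spec = md$spec, fixed_names = colnames(md$X),
                 scaling = md$scaling, mesh = md$mesh, nv = md$nv,
                 n = n, seed = seed),
            class = "herd_draws")
}

#' Extract one block's draws
#' @param draws a `herd_draws`.
#' @param block block name (`"fixed"`, `"spde"`, `"rw"`, `"st"`, ...).
#' @return matrix (n_draws x block size).
#' @export
draws_block <- function(draws, block) {
  r <- draws$blocks[draws$blocks$block == block, ]
  if (!nrow(r)) abort(paste0("block '", block, "' not in draws"))
  draws$latent[, seq(r$start, r$start + r$size - 1L), drop = FALSE]
}
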