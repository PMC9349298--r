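#' Stratified cross-validation folds within surveys
#'
#' Splits each survey's clusters into `k` folds (default 4, i.e. random 25%
#' hold-outs), distributed evenly among sampling strata defined by district
#' and urban/rural status: within every survey-stratum the fold sizes
#' differ by at most one. Strata with fewer clusters than folds fall back
#' to the same balanced-remainder rule (fold sizes as equal as possible)
#' and are noted.
#'
#' @param data cluster tibble with `cluster_id`, `survey_id`, `district`,
#'   `urban`.
#' @param fraction hold-out fraction; folds = `round(1/fraction)`.
#' @param strata character vector of stratum columns.
#' @param seed RNG seed; assignments are deterministic given it.
#' @return tibble `cluster_id`, `survey_id`, `fold`.
#' @export
make_folds <- function(data, fraction = 0.25, strata = c("district", "urban"),
                       seed = 1L) {
  k <- round(1 / fraction)
  if (k < 2) abort("fraction must give at least 2 folds")
  miss <- setdiff(strata, names(data))
  if (length(miss)) abort(paste0("stratum column(s) missing: ",
                                 paste(miss, collapse = ", ")))
  set.seed(seed)
  key <- interaction(data[strata], drop = TRUE)
  small <- names(which(table(interaction(data$survey_id, key, drop = TRUE)) < k))
  if (length(small))
    inform(paste0(length(small), " survey-stratum cell(s) have fewer than ",
                  k, " clusters; fold sizes made as equal as possible"))
  out <- data |>
    dplyr::mutate(.stratum = key) |>
    dplyr::group_by(.data$survey_id, .data$.stratum) |>
    dplyr::mutate(fold = {
      v <- rep_len(sample.int(k), dplyr::n())
      v[sample.int(length(v))]
    }) |>
    dplyr::ungroup()
  out[, c("cluster_id", "survey_id", "fold")]
}

#' Cross-validated mean squared error of candidate models
#'
#' For each fold, refits the model on the retained clusters and predicts
#' the held-out clusters' density (count per human) without iid effects,
#' mirroring the prediction protocol; scores
#' `MSE = mean((y_obs/D - y_pred)^2)` per survey within the hold-out.
#'
#' @param data cluster tibble.
#' @param mesh a `herd_mesh`.
#' @param spec a `herd_model_spec`.
#' @param folds from [make_folds()].
#' @param priors,control passed to [fit_zip_model()]; the fast MAP path is
#'   the default here.
#' @param mode `"global"` refits once per fold on all retained clusters
#'   (default); `"per_survey"` refits per survey x fold, leaving out only
#'   that survey's hold-out portion.
#' @param n_pred_draws posterior draws used for the held-out prediction.
#' @return `CvResult` tibble: `survey_id`, `model_id`, `fold`, `mse`,
#'   `n_holdout`, `failed`.
#' @export
cv_mse <- function(data, mesh, spec, folds, priors = default_priors(),
                   control = fit_control(method = "map"),
                   mode = c("global", "per_survey"), n_pred_draws = 200L) {
  mode <- match.arg(mode)
  data <- dplyr::left_join(as_tibble(data), folds, by = c("cluster_id", "survey_id"))
  if (anyNA(data$fold)) abort("folds do not cover all clusters")
  kf <- sort(unique(data$fold))
  if (control$method == "map") {
    # warm-start the per-fold refits from the full-data posterior mode
    fit0 <- tryCatch(fit_zip_model(data, mesh, spec, priors, control),
                     error = function(e) NULL)
    if (!is.null(fit0)) {
      control$init <- as.list(fit0$chain[1, ])
      control$map_maxit <- max(60L, control$map_maxit %/% 4L)
    }
  }
  res <- list()
  for (f in kf) {
    hold_all <- data[data$fold == f, ]
    train_sets <- if (mode == "global") list(global = data[data$fold != f, ])
      else setNames(lapply(unique(hold_all$survey_id), function(s)
        data[!(data$fold == f & data$survey_id == s), ]),
        unique(hold_all$survey_id))
    for (nm in names(train_sets)) {
      train <- train_sets[[nm]]
      hold <- if (mode == "global") hold_all
              else hold_all[hold_all$survey_id == nm, ]
      pred <- tryCatch({
        fit <- fit_zip_model(train, mesh, spec, priors, control)
        dr <- posterior_sample(fit, n = n_pred_draws,
                               seed = control$seed + 17L, include_iid = FALSE)
        predict_clusters(dr, hold)
      }, error = function(e) e)
      if (inherits(pred, "error")) {
        res[[length(res) + 1L]] <- hold |>
          dplyr::count(.data$survey_id, name = "n_holdout") |>
          dplyr::mutate(model_id = spec$model, fold = f, mse = NA_real_,
                        failed = TRUE)
        warn(paste0("prediction failed for fold ", f, ": ",
                    conditionMessage(pred)))
      } else {
        obs <- hold$livestock_count / hold$human_count
        res[[length(res) + 1L]] <- tibble(survey_id = hold$survey_id,
                                          err2 = (obs - pred)^2) |>
          dplyr::group_by(.data$survey_id) |>
          dplyr::summarise(mse = mean(.data$err2), n_holdout = dplyr::n(),
                           .groups = "drop") |>
          dplyr::mutate(model_id = spec$model, fold = f, failed = FALSE)
      }
    }
  }
  dplyr::bind_rows(res)[, c("survey_id", "model_id", "fold", "mse",
                            "n_holdout", "failed")]
}

# posterior-median density prediction at cluster locations (no iid, no offset
# exponent: density = count per human, then compared to y/D)
predict_clusters <- function(draws, clusters) {
  spec <- draws$spec
  n <- nrow(clusters)
  Xg <- matrix(1, n, 1L)
  for (v in setdiff(spec$fixed_effects, "intercept")) {
    col <- as.numeric(clusters[[v]])
    if (v %in% names(draws$scaling)) {
      sc <- draws$scaling[[v]]
      col <- (col - sc["center"]) / sc["scale"]
    }
    Xg <- cbind(Xg, col)
  }
  eta <- tcrossprod(draws_block(draws, "fixed"), Xg)
  if (isTRUE(spec$effects$spde) || isTRUE(spec$effects$spacetime))
    Ag <- project_points(draws$mesh, cbind(clusters$lon, clusters$lat))
  if (isTRUE(spec$effects$spde))
    eta <- eta + tcrossprod(draws_block(draws, "spde"), Ag)
  t_i <- match(clusters$year, draws$years)
  if (anyNA(t_i)) abort("held-out year outside the fitted span")
  if (isTRUE(spec$effects$rw))
    eta <- eta + draws_block(draws, "rw")[, t_i, drop = FALSE]
  if (isTRUE(spec$effects$spacetime)) {
    st <- draws_block(draws, "st")
    for (tt in unique(t_i)) {
      idx <- which(t_i == tt)
      cols <- ((tt - 1L) * draws$nv + 1L):(tt * draws$nv)
      eta[, idx] <- eta[, idx] +
        tcrossprod(st[, cols, drop = FALSE], Ag[idx, , drop = FALSE])
    }
  }
  apply(exp(eta), 2L, median)
}

#' Run the six-model menu through cross-validation
#'
#' @inheritParams cv_mse
#' @param models integer vector of menu ids (1-6).
#' @param restricted use the restricted random-effect set for every model.
#' @param species species label.
#' @return combined `CvResult` tibble over models.
#' @export
cv_model_menu <- function(data, mesh, folds, models = 1:6, restricted = FALSE,
                          species = "cattle", priors = default_priors(),
                          control = fit_control(method = "map")) {
  purrr::map_dfr(models, function(m)
    cv_mse(data, mesh, model_spec(m, species = species, restricted = restricted),
           folds, priors, control))
}

#' Select the model with minimal cluster-weighted mean MSE
#'
#' Ties (exact equality of the weighted mean) are broken toward the model
#' with fewer fixed effects, then the smaller id.
#'
#' @param cv_tbl a `CvResult` tibble.
#' @return list with `model_id` and the per-model summary tibble.
#' @export
select_model <- function(cv_tbl) {
  if (!nrow(cv_tbl)) abort("empty CV table")
  ok <- cv_tbl[!is.na(cv_tbl$mse), ]
  if (!nrow(ok)) abort("no successful CV results")
  summ <- ok |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(
      mean_mse = sum(.data$mse * .data$n_holdout) / sum(.data$n_holdout),
      n = sum(.data$n_holdout), .groups = "drop") |>
    dplyr::mutate(n_fixed = vapply(.data$model_id,
                                   function(m) n_fixed_effects(model_spec(m)),
                                   integer(1))) |>
    dplyr::arrange(.data$mean_mse, .data$n_fixed, .data$model_id)
  list(model_id = summ$model_id[1], summary = summ)
}

#' Box plot of hold-out MSE by candidate model
#' @param cv_tbl a `CvResult` tibble from [cv_mse()] or [cv_model_menu()].
#' @return a ggplot object.
#' @export
plot_cv <- function(cv_tbl) {
  ggplot2::ggplot(cv_tbl[!is.na(cv_tbl$mse), ],
                  ggplot2::aes(x = factor(.data$model_id), y = .data$mse)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "model", y = "hold-out MSE (density scale)")
}
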