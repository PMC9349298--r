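#' Fit the urbanicity classifier
#'
#' Logistic regression of cluster urban/rural labels on population density
#' and nighttime lights, with a random 2/3 training, 1/3 test split.
#' Reported accuracies are per class (rural and urban separately) on the
#' held-out third only.
#'
#' @param data tibble with `urban` (0/1), `popdensity`, `nightlights`.
#' @param split_seed seed for the train/test split.
#' @param threshold classification probability threshold (default 0.5).
#' @param train_fraction training share (default 2/3).
#' @return object of class `herd_urban_model`: glm fit, coefficients,
#'   threshold, and an `accuracy` tibble (class, accuracy, n_test).
#' @export
fit_urban <- function(data, split_seed = 1L, threshold = 0.5,
                      train_fraction = 2 / 3) {
  d <- as_tibble(data)
  need <- c("urban", "popdensity", "nightlights")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  set.seed(split_seed)
  n <- nrow(d)
  idx_train <- sample.int(n, round(train_fraction * n))
  train <- d[idx_train, ]; test <- d[-idx_train, ]
  if (length(unique(train$urban)) < 2L)
    abort("training split contains a single class; cannot fit the classifier")
  fit <- suppressWarnings(
    glm(urban ~ popdensity + nightlights, family = binomial(), data = train))
  prob <- predict(fit, newdata = test, type = "response")
  pred <- as.numeric(prob >= threshold)
  acc <- tibble(class = c("rural", "urban")) |>
    dplyr::mutate(
      n_test = c(sum(test$urban == 0), sum(test$urban == 1)),
      accuracy = c(mean(pred[test$urban == 0] == 0),
                   mean(pred[test$urban == 1] == 1)))
  structure(list(fit = fit, coefficients = stats::coef(fit),
                 threshold = threshold, accuracy = acc,
                 n_train = length(idx_train), n_test = n - length(idx_train),
                 split_seed = split_seed),
            class = "herd_urban_model")
}

#' @export
print.herd_urban_model <- function(x, ...) {
  cat("<herd_urban_model> logistic(popdensity, nightlights), threshold ",
      x$threshold, "\n", sep = "")
  cat("  train/test: ", x$n_train, "/", x$n_test, "\n", sep = "")
  print(x$accuracy)
  invisible(x)
}

#' @export
tidy.herd_urban_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.herd_urban_model <- function(x, ...) {
  tibble(n_train = x$n_train, n_test = x$n_test,
         accuracy_rural = x$accuracy$accuracy[x$accuracy$class == "rural"],
         accuracy_urban = x$accuracy$accuracy[x$accuracy$class == "urban"],
         threshold = x$threshold)
}

#' Classify a raster into a binary urban/rural surface
#'
#' Applies the fitted logistic model cell-wise to aligned population-density
#' and nighttime-lights rasters and thresholds the predicted probability.
#'
#' @param model a `herd_urban_model`.
#' @param covariates a `herd_raster` with `popdensity` and `nightlights`
#'   layers (one aligned grid).
#' @return the raster with an added binary `urban_pred` layer.
#' @export
predict_urban_surface <- function(model, covariates) {
  r <- covariates
  if (!all(c("popdensity", "nightlights") %in% names(r)))
    abort("covariate raster must carry popdensity and nightlights layers")
  prob <- predict(model$fit,
                  newdata = r[, c("popdensity", "nightlights")],
                  type = "response")
  r$urban_pred <- as.numeric(prob >= model$threshold)
  r
}

#' Check that two rasters share one grid
#' @keywords internal
check_aligned <- function(a, b) {
  ma <- raster_meta(a); mb <- raster_meta(b)
  if (!isTRUE(all.equal(ma$origin, mb$origin)) ||
      !isTRUE(all.equal(ma$resolution, mb$resolution)) ||
      ma$ncol != mb$ncol || ma$nrow != mb$nrow)
    abort("rasters are not aligned (origin/resolution/dimensions differ)")
  invisible(TRUE)
}
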