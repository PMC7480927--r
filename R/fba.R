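#' FBA model configuration
#'
#' Hyperparameter grid and cross-validation settings for the support-vector
#' regression of age. The grid is searched by grouped inner
#' cross-validation (folds split by infant so serial recordings never
#' straddle a fold).
#'
#' @param cost_grid SVR cost values C.
#' @param gamma_scale_grid RBF gamma values, as multiples of `1/n_features`.
#' @param epsilon_grid Epsilon-tube half-widths (weeks).
#' @param inner_folds Number of inner CV folds for tuning.
#' @param tune If `FALSE`, fit directly with the first grid point.
#' @return A list of class `fba_config`.
#' @export
fba_config <- function(cost_grid = c(1, 10, 100),
                       gamma_scale_grid = c(0.01, 0.1, 1),
                       epsilon_grid = c(0.25, 0.5, 1),
                       inner_folds = 3, tune = TRUE) {
  structure(as.list(environment()), class = "fba_config")
}

feature_matrix <- function(features, feature_names) {
  missing <- setdiff(feature_names, names(features))
  if (length(missing) > 0)
    abort(sprintf("feature table lacks columns: %s",
                  paste(missing, collapse = ", ")),
          class = "neofba_contract_error")
  as.matrix(features[, feature_names, drop = FALSE])
}

# infant-grouped fold assignment: every infant's epochs land in one fold
grouped_folds <- function(infant_ids, k, seed) {
  infants <- unique(infant_ids)
  shuffled <- with_seed(seed, sample(infants))
  fold_of <- setNames(rep(seq_len(k), length.out = length(shuffled)), shuffled)
  unname(fold_of[as.character(infant_ids)])
}

fit_svr <- function(x, y, cost, gamma, epsilon) {
  fit <- e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
                    cost = cost, gamma = gamma, epsilon = epsilon,
                    scale = FALSE, fitted = FALSE)
  # a target constant within the epsilon tube leaves no support vectors;
  # the fitted function is then just the offset
  if (fit$tot.nSV == 0)
    return(structure(list(constant = mean(y)), class = "svr_constant"))
  fit
}

#' @export
predict.svr_constant <- function(object, newdata, ...) {
  rep(object$constant, nrow(as.matrix(newdata)))
}

#' Train the functional brain age regressor
#'
#' Features are imputed (training median), z-scored with training statistics
#' and fed to an RBF-kernel support-vector regression of PMA.
#' Hyperparameters are selected by infant-grouped inner cross-validation
#' over the configured grid (lowest RMSE); constant features are dropped
#' with a note in `training_meta`.
#'
#' @param features Tibble with the columns of [qeeg_feature_names()] plus
#'   `pma_weeks` and `infant_id`, one row per epoch (e.g. from
#'   [extract_cohort_features()]).
#' @param config An [fba_config()].
#' @param seed Seed for inner fold assignment.
#' @param feature_names Feature columns to use.
#' @return An object of class `fba_model`: standardisation parameters,
#'   imputation values, the fitted SVR, chosen hyperparameters and
#'   `training_meta`.
#' @export
train_fba <- function(features, config = fba_config(), seed = 1,
                      feature_names = qeeg_feature_names()) {
  features <- tibble::as_tibble(features)
  if (!"pma_weeks" %in% names(features))
    stop_input("features must carry pma_weeks")
  ages <- features$pma_weeks
  if (length(ages) < 10) stop_input("need >= 10 training epochs")
  if (!all(is.finite(ages))) stop_input("ages must be finite")
  infant_ids <- features$infant_id %||% as.character(seq_along(ages))

  x <- feature_matrix(features, feature_names)
  if (nrow(x) != length(ages))
    abort("feature/age row mismatch", class = "neofba_contract_error")

  imputation <- apply(x, 2, median, na.rm = TRUE)
  imputation[!is.finite(imputation)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- imputation[j]

  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) == ncol(x))
    abort("all features are constant; cannot fit", class = "neofba_fit_error")
  if (length(dropped) > 0) {
    warn(sprintf("dropping constant features: %s",
                 paste(dropped, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  used <- colnames(x)
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  z <- sweep(sweep(x, 2, center), 2, scale_, `/`)

  grid <- expand.grid(cost = config$cost_grid,
                      gamma = config$gamma_scale_grid / ncol(z),
                      epsilon = config$epsilon_grid)
  if (config$tune && nrow(grid) > 1 &&
      length(unique(infant_ids)) >= config$inner_folds) {
    folds <- grouped_folds(infant_ids, config$inner_folds, seed)
    rmse <- vapply(seq_len(nrow(grid)), function(g) {
      errs <- unlist(lapply(seq_len(config$inner_folds), function(f) {
        tr <- folds != f
        if (all(tr) || !any(tr)) return(numeric())
        fit <- fit_svr(z[tr, , drop = FALSE], ages[tr],
                       grid$cost[g], grid$gamma[g], grid$epsilon[g])
        predict(fit, z[!tr, , drop = FALSE]) - ages[!tr]
      }))
      sqrt(mean(errs^2))
    }, 0)
    best <- grid[which.min(rmse), ]
  } else best <- grid[1, ]

  fit <- fit_svr(z, ages, best$cost, best$gamma, best$epsilon)
  structure(list(
    feature_names = used,
    center = center, scale = scale_,
    imputation = imputation,
    fit = fit,
    hyper = as.list(best),
    training_meta = list(seed = seed, n_epochs = nrow(z),
                         n_infants = length(unique(infant_ids)),
                         dropped_features = dropped,
                         grid = grid)
  ), class = "fba_model")
}

#' @export
print.fba_model <- function(x, ...) {
  cat(sprintf(
    "<fba_model> %d features, %d epochs; C=%g gamma=%.4g epsilon=%g\n",
    length(x$feature_names), x$training_meta$n_epochs,
    x$hyper$cost, x$hyper$gamma, x$hyper$epsilon))
  invisible(x)
}

#' @export
glance.fba_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$feature_names),
                 n_epochs = x$training_meta$n_epochs,
                 n_infants = x$training_meta$n_infants,
                 cost = x$hyper$cost, gamma = x$hyper$gamma,
                 epsilon = x$hyper$epsilon)
}

predict_epochs <- function(model, features) {
  x <- feature_matrix(features, model$feature_names)
  for (j in seq_len(ncol(x)))
    x[is.na(x[, j]), j] <- model$imputation[model$feature_names[j]]
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)
  as.numeric(predict(model$fit, z))
}

#' Predict functional brain age
#'
#' Per-epoch predictions, averaged to one FBA per recording — the recording
#' summary mirrors averaging the model output over consecutive one-hour
#' epochs. Feature columns are matched by name; missing values are imputed
#' from the model's stored training medians.
#'
#' @param model An [train_fba()] model.
#' @param features Epoch feature tibble with a `recording_id` column.
#' @return A tibble, one row per recording: `recording_id`, `fba_weeks`,
#'   `n_epochs_used` and a `per_epoch_weeks` list-column.
#' @export
predict_fba <- function(model, features) {
  features <- tibble::as_tibble(features)
  if (!"recording_id" %in% names(features))
    stop_input("features must carry recording_id")
  features$.pred <- predict_epochs(model, features)
  features |>
    dplyr::group_by(.data$recording_id) |>
    dplyr::summarise(fba_weeks = mean(.data$.pred),
                     n_epochs_used = dplyr::n(),
                     per_epoch_weeks = list(.data$.pred),
                     .groups = "drop")
}

#' Leave-one-infant-out cross-validated FBA
#'
#' One fold per infant: all of an infant's recordings are predicted by a
#' model trained (including hyperparameter tuning) on the remaining
#' infants, so serial recordings of the same infant can never leak between
#' training and test. A per-recording mode (`unit = "recording"`) is
#' available for comparison.
#'
#' @param features Epoch feature tibble with `recording_id`, `infant_id`,
#'   `pma_weeks` and the feature columns.
#' @param config An [fba_config()].
#' @param seed Seed for inner-fold assignment.
#' @param unit Cross-validation unit: `"infant"` (default) or `"recording"`.
#' @return A tibble of class `fba_loocv`, one row per recording:
#'   `recording_id`, `infant_id`, `pma_weeks`, `fba_weeks`,
#'   `n_epochs_used`, `fold`.
#' @export
loo_cv <- function(features, config = fba_config(), seed = 1,
                   unit = c("infant", "recording")) {
  unit <- match.arg(unit)
  features <- tibble::as_tibble(features)
  need <- c("recording_id", "infant_id", "pma_weeks")
  if (!all(need %in% names(features)))
    stop_input("features must carry recording_id, infant_id, pma_weeks")
  key <- if (unit == "infant") features$infant_id else features$recording_id
  units <- unique(key)
  if (length(units) < 3) stop_input("need >= 3 cross-validation units")

  out <- purrr::map_dfr(seq_along(units), function(f) {
    test <- key == units[f]
    model <- train_fba(features[!test, , drop = FALSE], config = config,
                       seed = seed)
    preds <- predict_fba(model, features[test, , drop = FALSE])
    meta <- features[test, c("recording_id", "infant_id", "pma_weeks")] |>
      dplyr::distinct()
    dplyr::left_join(meta, preds[, c("recording_id", "fba_weeks",
                                     "n_epochs_used")],
                     by = "recording_id") |>
      dplyr::mutate(fold = f)
  })
  structure(out, class = c("fba_loocv", class(out)))
}

#' @export
glance.fba_loocv <- function(x, ...) {
  err <- x$fba_weeks - x$pma_weeks
  tibble::tibble(n_recordings = nrow(x),
                 n_infants = length(unique(x$infant_id)),
                 pearson_r = cor(x$fba_weeks, x$pma_weeks),
                 systematic_error = mean(err),
                 random_error = sd(err))
}
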