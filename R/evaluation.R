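#' Participant-grouped k-fold assignment
#'
#' Every record of a participant shares one fold, so no participant can
#' appear on both sides of a train/test split; fold sizes differ by at most
#' one participant. Deterministic given the seed.
#'
#' @param participants Character vector of participant ids (duplicates fine).
#' @param k Number of folds.
#' @param seed Integer seed for the participant shuffle.
#' @return Tibble with `participant_id`, `fold`.
#' @export
group_kfold <- function(participants, k = 5L, seed = 0L) {
  ids <- sort(unique(as.character(participants)))
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > length(ids)) {
    stop("k (", k, ") exceeds the number of distinct participants (",
         length(ids), ")", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  shuffled <- sample(ids)
  tibble::tibble(participant_id = shuffled,
                 fold = rep_len(seq_len(k), length(ids))) |>
    dplyr::arrange(.data$participant_id)
}

#' Leakage-free out-of-fold predictions
#'
#' Each row's prediction comes from a calibrator fitted without any row of
#' that row's participant (`x = t_test`, `y = t_ref`). For Deming, the error
#' variance ratio is re-estimated from the training rows of each fold.
#'
#' @param pairs A paired tibble ([pair_replicates()]).
#' @param spec A [calibrator_spec()].
#' @param folds A [group_kfold()] assignment covering every participant.
#' @param min_train Minimum training rows per fold.
#' @return `pairs` with added columns `.fold` and `.pred`.
#' @export
cross_validated_predictions <- function(pairs, spec, folds, min_train = 10L) {
  missing_ids <- setdiff(unique(pairs$participant_id), folds$participant_id)
  if (length(missing_ids) > 0) {
    stop("participants without a fold: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  dat <- dplyr::left_join(pairs, folds, by = "participant_id") |>
    dplyr::rename(.fold = "fold")
  dat$.pred <- NA_real_
  for (f in sort(unique(dat$.fold))) {
    test_idx <- which(dat$.fold == f)
    train <- dat[-test_idx, ]
    stopifnot(length(intersect(unique(train$participant_id),
                               unique(dat$participant_id[test_idx]))) == 0L)
    if (nrow(train) < min_train) {
      stop("fold ", f, " leaves only ", nrow(train),
           " training rows (< ", min_train, ")", call. = FALSE)
    }
    delta <- if (spec$model == "deming" && is.null(spec$params$delta)) {
      estimate_error_variance_ratio(train)
    } else NULL
    model <- fit_calibrator(spec, train$t_test, train$t_ref, delta = delta)
    dat$.pred[test_idx] <- predict(model, dat$t_test[test_idx])
  }
  dat
}

#' Calibration performance metrics
#'
#' With prediction errors `e = y_pred - y_true`: MAE, RMSE, bias (mean
#' error), `R^2 = 1 - sum(e^2) / sum((y_true - mean(y_true))^2)`, and the
#' Bland-Altman 95% limits of agreement of the errors,
#' `bias +/- 1.96 * sd(e)`.
#'
#' @param y_true,y_pred Equal-length numeric vectors (degC).
#' @param model_name Label for the output row.
#' @return One-row tibble: `model`, `n`, `mae`, `rmse`, `r2`, `bias`,
#'   `sd_error`, `loa_lower`, `loa_upper`.
#' @export
compute_metrics <- function(y_true, y_pred, model_name = "model") {
  stopifnot(length(y_true) == length(y_pred))
  n <- length(y_true)
  if (n < 2L) stop("metrics need n >= 2", call. = FALSE)
  if (stats::var(y_true) == 0) {
    stop("R^2 undefined: zero variance in y_true", call. = FALSE)
  }
  e <- y_pred - y_true
  bias <- mean(e)
  sde <- stats::sd(e)
  tibble::tibble(
    model = model_name, n = n,
    mae = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    r2 = 1 - sum(e^2) / sum((y_true - mean(y_true))^2),
    bias = bias, sd_error = sde,
    loa_lower = bias - 1.96 * sde,
    loa_upper = bias + 1.96 * sde
  )
}

#' Split-conformal prediction intervals from absolute residuals
#'
#' `q` is the `ceiling((m+1)*(1-alpha))`-th smallest of the `m` calibration
#' absolute residuals (infinite when the index exceeds `m`); the interval is
#' `point +/- q`. Guarantees marginal coverage >= 1 - alpha for exchangeable
#' calibration and test data.
#'
#' @param point_preds Numeric vector of point predictions.
#' @param calibration_abs_residuals Absolute residuals from a held-out
#'   calibration set (m >= 1).
#' @param alpha Miscoverage level, default 0.05.
#' @return Tibble: `point`, `lower`, `upper`, `interval_source`.
#' @export
conformal_interval <- function(point_preds, calibration_abs_residuals,
                               alpha = 0.05) {
  m <- length(calibration_abs_residuals)
  if (m < 1L) stop("empty calibration residuals", call. = FALSE)
  idx <- ceiling((m + 1) * (1 - alpha))
  q <- if (idx > m) Inf else sort(calibration_abs_residuals)[idx]
  tibble::tibble(point = point_preds,
                 lower = point_preds - q, upper = point_preds + q,
                 interval_source = "conformal")
}

#' Hyperparameter search ranges
#'
#' The tuning grid per model family (exhaustive Cartesian ranges). Models with
#' no tunable hyperparameters (Deming, isotonic, weighted spline) have a
#' single-row grid.
#'
#' @param model Model name as in [calibrator_spec()].
#' @return A data frame, one row per configuration.
#' @export
default_grid <- function(model) {
  switch(model,
    polynomial_huber = expand.grid(degree = c(1L, 2L, 3L),
                                   alpha = c(1e-4, 1e-3, 1e-2),
                                   epsilon = c(1.1, 1.35, 1.5, 1.7)),
    spline_huber = expand.grid(n_knots = c(3L, 4L, 5L, 6L, 8L),
                               epsilon = c(1.2, 1.35, 1.5)),
    loess = expand.grid(frac = c(0.1, 0.2, 0.25, 0.3, 0.4, 0.5, 0.6),
                        robust_iters = c(0L, 1L, 3L)),
    quantile_gbrt = expand.grid(n_estimators = c(100L, 300L, 500L),
                                learning_rate = c(0.01, 0.05, 0.1),
                                max_depth = c(2L, 3L)),
    monotone_boost = expand.grid(n_estimators = c(100L, 300L, 500L),
                                 learning_rate = c(0.01, 0.05, 0.1),
                                 num_leaves = c(7L, 15L, 31L)),
    random_forest = expand.grid(n_estimators = c(100L, 300L, 500L),
                                min_samples_leaf = c(1L, 3L, 5L),
                                bootstrap = c(TRUE, FALSE)),
    extra_trees = expand.grid(n_estimators = c(100L, 300L, 500L),
                              min_samples_leaf = c(1L, 3L, 5L),
                              bootstrap = c(TRUE, FALSE)),
    data.frame(row.names = 1L)[1, , drop = FALSE]
  )
}

#' Grid search over a model family
#'
#' Exhaustive search over the configuration grid using the same grouped folds
#' for every configuration; selection by lowest out-of-fold MAE, ties broken
#' by lower RMSE then first-in-grid order.
#'
#' @inheritParams cross_validated_predictions
#' @param model Model family name.
#' @param grid Data frame of configurations; default [default_grid()].
#' @param seed Seed forwarded to stochastic fitters.
#' @return A list with `best_spec` and `results` (grid plus `mae`, `rmse`).
#' @export
grid_search <- function(pairs, model, folds, grid = default_grid(model),
                        seed = 0L) {
  if (nrow(grid) == 0L) stop("empty grid", call. = FALSE)
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    args <- as.list(grid[i, , drop = FALSE])
    spec <- do.call(calibrator_spec, c(list(model = model), args, seed = seed))
    cv <- cross_validated_predictions(pairs, spec, folds)
    m <- compute_metrics(cv$t_ref, cv$.pred, model)
    dplyr::bind_cols(tibble::as_tibble(grid[i, , drop = FALSE]),
                     m[, c("mae", "rmse")], config = i)
  })
  best_i <- rows$config[order(rows$mae, rows$rmse, rows$config)][1]
  best_spec <- do.call(calibrator_spec,
                       c(list(model = model),
                         as.list(grid[best_i, , drop = FALSE]), seed = seed))
  list(best_spec = best_spec, results = rows)
}

#' Deployment fit with interval machinery
#'
#' Refits the chosen calibrator on all rows. Quantile-capable models
#' (quantile GBRT, monotone boost) supply their own 95% intervals; point
#' estimators get split-conformal intervals calibrated on out-of-fold
#' absolute residuals from the grouped folds.
#'
#' @inheritParams cross_validated_predictions
#' @param alpha Miscoverage level for the intervals.
#' @return Object of class `"deployment"`: the fitted calibrator plus
#'   interval state (`interval_source`, `conformal_q`).
#' @export
fit_deployment <- function(pairs, spec, folds = NULL, alpha = 0.05) {
  delta <- if (spec$model == "deming" && is.null(spec$params$delta)) {
    estimate_error_variance_ratio(pairs)
  } else NULL
  model <- fit_calibrator(spec, pairs$t_test, pairs$t_ref, delta = delta)
  if (has_quantile_intervals(spec)) {
    out <- list(calibrator = model, interval_source = "quantile_model",
                conformal_q = NA_real_, alpha = alpha)
  } else {
    if (is.null(folds)) folds <- group_kfold(pairs$participant_id, k = 5L)
    cv <- cross_validated_predictions(pairs, spec, folds)
    resid <- abs(cv$t_ref - cv$.pred)
    m <- length(resid)
    idx <- ceiling((m + 1) * (1 - alpha))
    q <- if (idx > m) Inf else sort(resid)[idx]
    out <- list(calibrator = model, interval_source = "conformal",
                conformal_q = q, alpha = alpha)
  }
  structure(out, class = "deployment")
}

#' @export
predict.deployment <- function(object, newdata, ...) {
  if (object$interval_source == "quantile_model") {
    quantile_interval(object$calibrator, newdata)
  } else {
    point <- predict(object$calibrator, newdata)
    tibble::tibble(point = point,
                   lower = point - object$conformal_q,
                   upper = point + object$conformal_q,
                   interval_source = "conformal")
  }
}

#' @export
print.deployment <- function(x, ...) {
  cat(sprintf("<deployment: %s> interval source: %s",
              x$calibrator$spec$model, x$interval_source))
  if (x$interval_source == "conformal") {
    cat(sprintf(" (q = %.3f degC at alpha = %.2f)", x$conformal_q, x$alpha))
  }
  cat("\n")
  invisible(x)
}

#' Run the full calibration suite
#'
#' Out-of-fold metrics for every specification (plus an uncalibrated `raw`
#' reference row where the prediction is the test reading itself), all using
#' identical fold assignments.
#'
#' @inheritParams cross_validated_predictions
#' @param specs List of [calibrator_spec()]; default all ten.
#' @param include_raw Include the uncalibrated reference row.
#' @return A tibble of class `"calibration_suite"`, one metrics row per
#'   model; per-model out-of-fold predictions in `attr(, "predictions")`.
#' @export
run_calibration_suite <- function(pairs, specs = default_calibrator_specs(),
                                  folds = NULL, include_raw = TRUE) {
  if (is.null(folds)) folds <- group_kfold(pairs$participant_id, k = 5L)
  preds <- list()
  rows <- list()
  if (include_raw) {
    rows$raw <- compute_metrics(pairs$t_ref, pairs$t_test, "raw")
    preds$raw <- dplyr::mutate(pairs, .pred = .data$t_test)
  }
  for (spec in specs) {
    cv <- cross_validated_predictions(pairs, spec, folds)
    rows[[spec$model]] <- compute_metrics(cv$t_ref, cv$.pred, spec$model)
    preds[[spec$model]] <- cv
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "predictions") <- preds
  attr(out, "folds") <- folds
  class(out) <- c("calibration_suite", class(out))
  out
}

#' @export
glance.calibration_suite <- function(x, ...) {
  best_mae <- x$model[which.min(x$mae)]
  best_rmse <- x$model[which.min(x$rmse)]
  tibble::tibble(n_models = sum(x$model != "raw"),
                 best_mae_model = best_mae, best_mae = min(x$mae),
                 best_rmse_model = best_rmse, best_rmse = min(x$rmse))
}
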