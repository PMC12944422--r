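#' Calibrator specification
#'
#' Identifies one of the ten calibration model families and its
#' hyperparameters. Defaults are the selected configurations of the
#' calibration suite; see [default_calibrator_specs()] for the full set and
#' [default_grid()] for the tuning ranges.
#'
#' @param model One of `"polynomial_huber"`, `"deming"`, `"isotonic"`,
#'   `"spline_huber"`, `"loess"`, `"weighted_spline"`, `"quantile_gbrt"`,
#'   `"monotone_boost"`, `"random_forest"`, `"extra_trees"`.
#' @param ... Hyperparameter overrides (name = value).
#' @param seed Integer seed for stochastic fitters (boosting, forests).
#' @return A list of class `"calibrator_spec"` with `model`, `params`, `seed`.
#' @export
calibrator_spec <- function(model, ..., seed = 0L) {
  model <- match.arg(model, c(
    "polynomial_huber", "deming", "isotonic", "spline_huber", "loess",
    "weighted_spline", "quantile_gbrt", "monotone_boost",
    "random_forest", "extra_trees"))
  defaults <- switch(model,
    polynomial_huber = list(degree = 2L, epsilon = 1.35, alpha = 0),
    deming           = list(delta = NULL),
    isotonic         = list(),
    spline_huber     = list(n_knots = 6L, epsilon = 1.35),
    loess            = list(frac = 0.25, robust_iters = 1L),
    weighted_spline  = list(n_knots = 6L, n_bins = 10L),
    quantile_gbrt    = list(n_estimators = 400L, learning_rate = 0.05,
                            max_depth = 3L),
    monotone_boost   = list(n_estimators = 600L, learning_rate = 0.03,
                            num_leaves = 31L),
    random_forest    = list(n_estimators = 400L, min_samples_leaf = 5L,
                            bootstrap = TRUE),
    extra_trees      = list(n_estimators = 400L, min_samples_leaf = 5L,
                            bootstrap = FALSE)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown hyperparameter(s) for ", model, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(list(model = model, params = defaults, seed = as.integer(seed)),
            class = "calibrator_spec")
}

#' The ten default calibrator specifications
#'
#' @param seed Master seed forwarded to the stochastic fitters.
#' @return Named list of [calibrator_spec()] objects.
#' @export
default_calibrator_specs <- function(seed = 0L) {
  models <- c("polynomial_huber", "deming", "isotonic", "spline_huber",
              "loess", "weighted_spline", "quantile_gbrt", "monotone_boost",
              "random_forest", "extra_trees")
  stats::setNames(lapply(models, calibrator_spec, seed = seed), models)
}

# ---- shared internals -------------------------------------------------------

.new_calibrator <- function(spec, fit, x, extra = list()) {
  structure(
    c(list(spec = spec, fit = fit, x_range = range(x), n = length(x)), extra),
    class = c(paste0("calib_", spec$model), "calibrator")
  )
}

# Iteratively reweighted least squares under Huber loss. X must carry an
# intercept in column 1 (never penalised). Scale is re-estimated each pass
# as 1.4826 * median |residual|; weights w_i = min(1, epsilon*s / |r_i|).
.huber_irls <- function(X, y, epsilon, alpha = 0, max_iter = 200L, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(c(0, rep(alpha, p - 1L)), p)
  beta <- solve(crossprod(X) + pen, crossprod(X, y))
  for (it in seq_len(max_iter)) {
    r <- drop(y - X %*% beta)
    s <- 1.4826 * stats::median(abs(r))
    if (s < 1e-12) return(list(coef = drop(beta), iterations = it, scale = s))
    w <- pmin(1, epsilon * s / abs(r))
    Xw <- X * w
    beta_new <- solve(crossprod(Xw, X) + pen, crossprod(Xw, y))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) return(list(coef = drop(beta), iterations = it, scale = s))
  }
  stop("Huber IRLS did not converge in ", max_iter,
       " iterations (last max coefficient change ", signif(delta, 3), ")",
       call. = FALSE)
}

# Natural-spline knot layout: n_knots quantile-spaced knots in total, the
# outer two serving as boundary knots.
.spline_knots <- function(x, n_knots) {
  ks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_knots),
                               names = FALSE))
  if (length(ks) < 2L) stop("degenerate predictor: all x identical", call. = FALSE)
  list(boundary = range(ks), internal = ks[-c(1L, length(ks))])
}

.spline_basis <- function(x, knots) {
  if (length(knots$internal) > 0) {
    b <- splines::ns(x, knots = knots$internal, Boundary.knots = knots$boundary)
  } else {
    b <- splines::ns(x, df = 1L, Boundary.knots = knots$boundary)
  }
  cbind(1, unclass(b))
}

# ---- robust polynomial ------------------------------------------------------

#' Robust polynomial calibration (Huber loss)
#'
#' Polynomial basis of the given degree on the standardised predictor, fitted
#' by iteratively reweighted least squares under Huber loss with optional
#' ridge penalty. Defaults: degree 2, epsilon 1.35, alpha 0.
#'
#' @param x,y Training readings (test instrument, reference instrument), degC.
#' @param degree Polynomial degree.
#' @param epsilon Huber robustness parameter (transition in scale units).
#' @param alpha Ridge penalty on the non-intercept coefficients.
#' @return A fitted `"calibrator"`.
#' @export
fit_polynomial_huber <- function(x, y, degree = 2L, epsilon = 1.35, alpha = 0) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n <= degree + 1L) stop("need n > degree + 1", call. = FALSE)
  mx <- mean(x); sx <- stats::sd(x)
  if (sx == 0) sx <- 1
  xs <- (x - mx) / sx
  X <- outer(xs, 0:degree, `^`)
  res <- .huber_irls(X, y, epsilon = epsilon, alpha = alpha)
  .new_calibrator(
    calibrator_spec("polynomial_huber", degree = degree, epsilon = epsilon,
                    alpha = alpha),
    fit = list(coef = res$coef, center = mx, scale = sx, degree = degree),
    x = x
  )
}

# ---- Deming -----------------------------------------------------------------

#' Error variance ratio from replicate variances
#'
#' `delta = (pooled within-participant replicate variance, reference) /
#' (pooled within-participant replicate variance, test)`, pooling by the mean
#' of per-cell variances across participants and rounds. This is the ratio of
#' the response-side to predictor-side error variance needed by Deming
#' regression when calibrating test readings to the reference.
#'
#' @param table A long measurement tibble, or a paired tibble from
#'   [pair_replicates()] (columns `t_test`, `t_ref`).
#' @return `delta` (numeric scalar).
#' @export
estimate_error_variance_ratio <- function(table) {
  if (all(c("t_test", "t_ref") %in% names(table))) {
    cell_vars <- table |>
      dplyr::group_by(.data$participant_id, .data$round) |>
      dplyr::summarise(v_test = stats::var(.data$t_test),
                       v_ref = stats::var(.data$t_ref),
                       n = dplyr::n(), .groups = "drop")
    if (any(cell_vars$n < 2L)) {
      stop("need >= 2 replicates per (participant, round) cell", call. = FALSE)
    }
    v_test <- mean(cell_vars$v_test)
    v_ref <- mean(cell_vars$v_ref)
  } else {
    cell_vars <- table |>
      dplyr::group_by(.data$participant_id, .data$round, .data$device) |>
      dplyr::summarise(v = stats::var(.data$temperature_c), n = dplyr::n(),
                       .groups = "drop")
    if (any(cell_vars$n < 2L)) {
      stop("need >= 2 replicates per (participant, round, device) cell",
           call. = FALSE)
    }
    v_test <- mean(cell_vars$v[cell_vars$device == "test"])
    v_ref <- mean(cell_vars$v[cell_vars$device == "reference"])
  }
  if (v_test <= 0) stop("zero test-device replicate variance", call. = FALSE)
  v_ref / v_test
}

#' Deming (errors-in-variables) regression
#'
#' Total-least-squares line accounting for measurement error in both
#' variables. With `delta = Var(y-error) / Var(x-error)` the slope is
#' `beta = (s_yy - delta*s_xx + sqrt((s_yy - delta*s_xx)^2 + 4*delta*s_xy^2))
#' / (2*s_xy)` and the intercept `mean(y) - beta*mean(x)`. As `delta -> Inf`
#' the fit approaches ordinary regression of y on x; as `delta -> 0` it
#' approaches the inverse of regressing x on y.
#'
#' @param x,y Training readings, degC.
#' @param delta Error variance ratio; see [estimate_error_variance_ratio()].
#' @return A fitted `"calibrator"` with `fit$slope`, `fit$intercept`.
#' @export
fit_deming <- function(x, y, delta = 1) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("Deming regression needs n >= 3", call. = FALSE)
  if (!is.finite(delta) || delta <= 0) stop("delta must be > 0", call. = FALSE)
  s_xx <- stats::var(x); s_yy <- stats::var(y); s_xy <- stats::cov(x, y)
  if (s_xy == 0) stop("undefined Deming slope: zero covariance", call. = FALSE)
  disc <- (s_yy - delta * s_xx)^2 + 4 * delta * s_xy^2
  slope <- (s_yy - delta * s_xx + sqrt(disc)) / (2 * s_xy)
  intercept <- mean(y) - slope * mean(x)
  .new_calibrator(
    calibrator_spec("deming", delta = delta),
    fit = list(slope = slope, intercept = intercept, delta = delta),
    x = x
  )
}

# ---- isotonic ---------------------------------------------------------------

#' Pool-adjacent-violators algorithm
#'
#' Weighted least-squares projection of `y` onto the cone of non-decreasing
#' sequences: repeatedly merges adjacent blocks whose weighted means violate
#' monotonicity. Exact solution of
#' `min sum(w_i (y_i - f_i)^2) s.t. f_1 <= ... <= f_n`.
#'
#' @param y Numeric response sequence (already ordered by the predictor).
#' @param w Positive weights, default all 1.
#' @return Numeric vector of fitted values, non-decreasing.
#' @export
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  stopifnot(length(w) == n, all(w > 0))
  if (n == 0L) return(numeric(0))
  # blocks as parallel stacks: value (weighted mean), weight, size
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      wsum <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / wsum
      wt[top - 1L] <- wsum
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], sz[seq_len(top)])
}

#' Isotonic calibration
#'
#' Non-decreasing step fit by [pava()] after sorting by `x` and collapsing
#' tied predictors to their weighted means. Prediction interpolates linearly
#' between knots and extends the boundary values outside the training range
#' (monotone by construction, never non-physical downward mappings).
#'
#' @param x,y Training readings, degC.
#' @param weights Optional positive case weights.
#' @return A fitted `"calibrator"`.
#' @export
fit_isotonic <- function(x, y, weights = rep(1, length(x))) {
  n <- length(x)
  stopifnot(length(y) == n, length(weights) == n)
  if (n < 2L) stop("isotonic regression needs n >= 2", call. = FALSE)
  o <- order(x)
  xo <- x[o]; yo <- y[o]; wo <- weights[o]
  # collapse ties in x (the fit must be constant on tied predictors)
  grp <- cumsum(c(TRUE, diff(xo) > 0))
  xu <- vapply(split(xo, grp), function(v) v[1], numeric(1))
  yu <- vapply(split(seq_along(yo), grp),
               function(ix) stats::weighted.mean(yo[ix], wo[ix]), numeric(1))
  wu <- vapply(split(wo, grp), sum, numeric(1))
  fit_vals <- pava(yu, wu)
  .new_calibrator(
    calibrator_spec("isotonic"),
    fit = list(knots_x = unname(xu), knots_y = unname(fit_vals)),
    x = x
  )
}

# ---- Huber spline -----------------------------------------------------------

#' Robust natural-spline calibration (Huber loss)
#'
#' Natural cubic spline with quantile-spaced knots, coefficients fitted by
#' Huber IRLS (scale from the median absolute residual). Defaults: 6 knots,
#' epsilon 1.35.
#'
#' @inheritParams fit_polynomial_huber
#' @param n_knots Total number of quantile-spaced knots (outer two are the
#'   boundary knots).
#' @return A fitted `"calibrator"`.
#' @export
fit_spline_huber <- function(x, y, n_knots = 6L, epsilon = 1.35) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n <= n_knots + 2L) stop("need n > n_knots + 2", call. = FALSE)
  knots <- .spline_knots(x, n_knots)
  X <- .spline_basis(x, knots)
  res <- .huber_irls(X, y, epsilon = epsilon)
  .new_calibrator(
    calibrator_spec("spline_huber", n_knots = n_knots, epsilon = epsilon),
    fit = list(coef = res$coef, knots = knots),
    x = x
  )
}

# ---- LOESS ------------------------------------------------------------------

# Local degree-1 weighted least squares at x0 over the k nearest neighbours
# with tricube distance weights times robustness multipliers.
.loess_point <- function(x0, x, y, rob, k) {
  d <- abs(x - x0)
  idx <- order(d)[seq_len(k)]
  h <- d[idx[k]]
  if (h == 0) {
    if (stats::sd(x[idx]) == 0 || all(d[idx] == 0)) {
      # all neighbours at x0 itself: weighted mean is the only defined fit
      if (length(unique(x[idx])) == 1L) {
        wr <- rob[idx]
        if (sum(wr) == 0) wr <- rep(1, length(idx))
        return(stats::weighted.mean(y[idx], wr))
      }
    }
    h <- max(d[idx])
  }
  w <- (1 - pmin(d[idx] / h, 1)^3)^3 * rob[idx]
  if (sum(w) == 0) w <- rep(1, length(idx))
  xi <- x[idx]; yi <- y[idx]
  xw <- stats::weighted.mean(xi, w); yw <- stats::weighted.mean(yi, w)
  sxx <- sum(w * (xi - xw)^2)
  if (sxx == 0) {
    if (stats::sd(xi) > 0) {
      stop("degenerate LOESS neighbourhood at x = ", signif(x0, 6), call. = FALSE)
    }
    return(yw)
  }
  b <- sum(w * (xi - xw) * (yi - yw)) / sxx
  yw + b * (x0 - xw)
}

#' Robust local linear (LOESS-style) calibration
#'
#' At each prediction point a degree-1 weighted least-squares fit over the
#' `ceiling(frac * n)` nearest training neighbours with tricube distance
#' weights; `robust_iters` bisquare reweighting passes downweight outliers.
#' Defaults: frac 0.25, one robustness iteration.
#'
#' @inheritParams fit_polynomial_huber
#' @param frac Neighbourhood fraction (span).
#' @param robust_iters Number of bisquare robustness passes.
#' @return A fitted `"calibrator"`.
#' @export
fit_loess_robust <- function(x, y, frac = 0.25, robust_iters = 1L) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- ceiling(frac * n)
  if (k < 3L) stop("frac * n must be >= 3 (got ", k, ")", call. = FALSE)
  rob <- rep(1, n)
  if (robust_iters > 0) {
    for (it in seq_len(robust_iters)) {
      fitted <- vapply(x, .loess_point, numeric(1), x = x, y = y, rob = rob, k = k)
      e <- y - fitted
      s <- 6 * stats::median(abs(e))
      if (s < 1e-12) break
      rob <- pmax(0, (1 - (e / s)^2))^2
    }
  }
  .new_calibrator(
    calibrator_spec("loess", frac = frac, robust_iters = robust_iters),
    fit = list(x = x, y = y, rob = rob, k = k),
    x = x
  )
}

# ---- weighted spline --------------------------------------------------------

#' Heteroscedasticity-weighted spline calibration
#'
#' Three stages: (1) a pilot isotonic fit supplies residuals; (2) the
#' predictor is partitioned into `n_bins` equal-count bins and the residual
#' variance per bin is estimated (floored at 1e-6 degC^2); (3) a natural
#' cubic spline is fitted by weighted least squares with inverse-variance
#' weights from the bin of each observation.
#'
#' @inheritParams fit_spline_huber
#' @param n_bins Number of equal-count predictor bins for the variance model.
#' @return A fitted `"calibrator"`.
#' @export
fit_weighted_spline <- function(x, y, n_knots = 6L, n_bins = 10L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2L * n_bins) {
    n_bins <- max(1L, floor(n / 2L))
    warning("too few points for requested bins; reduced to ", n_bins,
            call. = FALSE)
  }
  pilot <- fit_isotonic(x, y)
  resid <- y - predict(pilot, x)
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                   names = FALSE))
  if (length(breaks) < 2L) breaks <- range(x) + c(-1e-9, 1e-9)
  bin <- cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  levels_present <- sort(unique(bin))
  var_by_bin <- vapply(levels_present, function(b) {
    r <- resid[bin == b]
    if (length(r) < 2L) NA_real_ else stats::var(r)
  }, numeric(1))
  if (all(is.na(var_by_bin))) var_by_bin[] <- 1
  var_by_bin[is.na(var_by_bin)] <- mean(var_by_bin, na.rm = TRUE)
  var_by_bin <- pmax(var_by_bin, 1e-6)
  w <- 1 / var_by_bin[match(bin, levels_present)]
  knots <- .spline_knots(x, n_knots)
  X <- .spline_basis(x, knots)
  Xw <- X * w
  coef <- drop(solve(crossprod(Xw, X), crossprod(Xw, y)))
  .new_calibrator(
    calibrator_spec("weighted_spline", n_knots = n_knots, n_bins = n_bins),
    fit = list(coef = coef, knots = knots,
               bin_breaks = breaks, bin_var = var_by_bin),
    x = x
  )
}

# ---- boosted quantile models ------------------------------------------------

.xgb_matrix <- function(x) xgboost::xgb.DMatrix(matrix(x, ncol = 1L))

.fit_xgb_quantile <- function(x, y, tau, n_estimators, learning_rate,
                              max_depth = 3L, num_leaves = NULL, seed = 0L) {
  params <- list(objective = "reg:quantileerror", quantile_alpha = tau,
                 eta = learning_rate, seed = seed, nthread = 1L)
  if (is.null(num_leaves)) {
    params$max_depth <- max_depth
  } else {
    params$grow_policy <- "lossguide"
    params$max_leaves <- num_leaves
    params$max_depth <- 0L
  }
  dtrain <- xgboost::xgb.DMatrix(matrix(x, ncol = 1L), label = y)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = n_estimators, verbose = 0)
}

#' Quantile gradient-boosted calibration
#'
#' One boosted-tree model per quantile of the triplet, each minimising the
#' pinball loss `L_tau(r) = tau*max(r,0) + (tau-1)*min(r,0)`. The point
#' prediction is the 0.5-quantile model; the 0.025/0.975 models supply a 95%
#' interval, with quantile crossing repaired by sorting the three outputs per
#' point. Defaults: 400 estimators, learning rate 0.05, depth 3.
#'
#' @inheritParams fit_polynomial_huber
#' @param quantiles Quantile triplet (lower, median, upper).
#' @param n_estimators,learning_rate,max_depth Boosting hyperparameters.
#' @param seed Integer seed.
#' @return A fitted `"calibrator"` carrying one model per quantile.
#' @export
fit_quantile_boost <- function(x, y, quantiles = c(0.025, 0.5, 0.975),
                               n_estimators = 400L, learning_rate = 0.05,
                               max_depth = 3L, seed = 0L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 20L) stop("quantile boosting needs n >= 20", call. = FALSE)
  if (any(quantiles <= 0 | quantiles >= 1)) {
    stop("quantiles must lie strictly in (0, 1)", call. = FALSE)
  }
  quantiles <- sort(quantiles)
  models <- lapply(quantiles, function(tau) {
    .fit_xgb_quantile(x, y, tau, n_estimators, learning_rate,
                      max_depth = max_depth, seed = seed)
  })
  .new_calibrator(
    calibrator_spec("quantile_gbrt", n_estimators = n_estimators,
                    learning_rate = learning_rate, max_depth = max_depth,
                    seed = seed),
    fit = list(models = models, quantiles = quantiles),
    x = x
  )
}

#' Monotone boosted median calibration
#'
#' Gradient-boosted median (pinball loss at tau = 0.5) with a hard
#' non-decreasing constraint on the predictor, grown leaf-wise
#' (`num_leaves` leaves per tree); unconstrained 0.025/0.975 quantile models
#' supply the 95% interval. The constrained median uses a custom pinball
#' objective (gradient -tau / 1-tau, unit curvature) so the monotone bound
#' applies to every leaf value. Defaults: 600 estimators, learning rate
#' 0.03, 31 leaves.
#'
#' @inheritParams fit_quantile_boost
#' @param num_leaves Maximum leaves per tree (leaf-wise growth).
#' @return A fitted `"calibrator"`.
#' @export
fit_monotone_boost <- function(x, y, n_estimators = 600L, learning_rate = 0.03,
                               num_leaves = 31L, seed = 0L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 20L) stop("boosting needs n >= 20", call. = FALSE)
  base <- stats::median(y)
  pinball_obj <- function(preds, dtrain) {
    r <- xgboost::getinfo(dtrain, "label") - preds
    list(grad = ifelse(r > 0, -0.5, 0.5), hess = rep(1, length(r)))
  }
  dtrain <- xgboost::xgb.DMatrix(matrix(x, ncol = 1L), label = y)
  median_model <- xgboost::xgb.train(
    params = list(eta = learning_rate, grow_policy = "lossguide",
                  max_leaves = num_leaves, max_depth = 0L,
                  monotone_constraints = c(1), base_score = base,
                  seed = seed, nthread = 1L),
    data = dtrain, nrounds = n_estimators, obj = pinball_obj, verbose = 0)
  side <- lapply(c(0.025, 0.975), function(tau) {
    .fit_xgb_quantile(x, y, tau, n_estimators, learning_rate,
                      num_leaves = num_leaves, seed = seed)
  })
  .new_calibrator(
    calibrator_spec("monotone_boost", n_estimators = n_estimators,
                    learning_rate = learning_rate, num_leaves = num_leaves,
                    seed = seed),
    fit = list(models = list(side[[1]], median_model, side[[2]]),
               quantiles = c(0.025, 0.5, 0.975)),
    x = x
  )
}

# ---- tree ensembles ---------------------------------------------------------

#' Random forest / extra trees calibration
#'
#' Bagged (random forest) or extremely randomised (extra trees) regression
#' ensemble on the single predictor; the point prediction is the ensemble
#' mean and 95% intervals come from the conformal route (see
#' [fit_deployment()]). Defaults: 400 trees, minimum leaf size 5,
#' bootstrap on for the forest and off for extra trees.
#'
#' @inheritParams fit_polynomial_huber
#' @param kind `"random_forest"` or `"extra_trees"`.
#' @param n_estimators Number of trees.
#' @param min_samples_leaf Minimum node size.
#' @param bootstrap Sample rows with replacement per tree.
#' @param seed Integer seed.
#' @return A fitted `"calibrator"`.
#' @export
fit_tree_ensemble <- function(x, y, kind = c("random_forest", "extra_trees"),
                              n_estimators = 400L, min_samples_leaf = 5L,
                              bootstrap = NULL, seed = 0L) {
  kind <- match.arg(kind)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 10L) stop("tree ensembles need n >= 10", call. = FALSE)
  if (is.null(bootstrap)) bootstrap <- (kind == "random_forest")
  if (n_estimators < 1L || min_samples_leaf < 1L) {
    stop("invalid tree-ensemble hyperparameters", call. = FALSE)
  }
  fit <- ranger::ranger(
    y = y, x = data.frame(x = x),
    num.trees = n_estimators, min.node.size = min_samples_leaf,
    mtry = 1L,
    splitrule = if (kind == "extra_trees") "extratrees" else "variance",
    num.random.splits = 1L,
    replace = bootstrap, sample.fraction = 1,
    seed = seed, num.threads = 1L
  )
  .new_calibrator(
    calibrator_spec(kind, n_estimators = n_estimators,
                    min_samples_leaf = min_samples_leaf, bootstrap = bootstrap,
                    seed = seed),
    fit = list(forest = fit),
    x = x
  )
}

# ---- unified fit / predict --------------------------------------------------

#' Fit a calibrator from a specification
#'
#' Dispatches to the model-specific fitter. For `"deming"` with
#' `delta = NULL`, `delta` must be supplied here (e.g. from
#' [estimate_error_variance_ratio()] on the training data).
#'
#' @param spec A [calibrator_spec()].
#' @param x,y Training readings (test, reference), degC.
#' @param delta Error variance ratio for Deming regression.
#' @return A fitted `"calibrator"`.
#' @export
fit_calibrator <- function(spec, x, y, delta = NULL) {
  stopifnot(inherits(spec, "calibrator_spec"))
  p <- spec$params
  switch(spec$model,
    polynomial_huber = fit_polynomial_huber(x, y, degree = p$degree,
                                            epsilon = p$epsilon, alpha = p$alpha),
    deming = fit_deming(x, y, delta = delta %||% p$delta %||%
                          stop("Deming requires delta", call. = FALSE)),
    isotonic = fit_isotonic(x, y),
    spline_huber = fit_spline_huber(x, y, n_knots = p$n_knots,
                                    epsilon = p$epsilon),
    loess = fit_loess_robust(x, y, frac = p$frac, robust_iters = p$robust_iters),
    weighted_spline = fit_weighted_spline(x, y, n_knots = p$n_knots,
                                          n_bins = p$n_bins),
    quantile_gbrt = fit_quantile_boost(x, y, n_estimators = p$n_estimators,
                                       learning_rate = p$learning_rate,
                                       max_depth = p$max_depth, seed = spec$seed),
    monotone_boost = fit_monotone_boost(x, y, n_estimators = p$n_estimators,
                                        learning_rate = p$learning_rate,
                                        num_leaves = p$num_leaves,
                                        seed = spec$seed),
    random_forest = fit_tree_ensemble(x, y, "random_forest",
                                      n_estimators = p$n_estimators,
                                      min_samples_leaf = p$min_samples_leaf,
                                      bootstrap = p$bootstrap, seed = spec$seed),
    extra_trees = fit_tree_ensemble(x, y, "extra_trees",
                                    n_estimators = p$n_estimators,
                                    min_samples_leaf = p$min_samples_leaf,
                                    bootstrap = p$bootstrap, seed = spec$seed)
  )
}

.as_x <- function(newdata) {
  if (is.data.frame(newdata)) {
    if ("t_test" %in% names(newdata)) return(newdata$t_test)
    return(newdata[[1]])
  }
  as.numeric(newdata)
}

#' Predict from a fitted calibrator
#'
#' Point predictions (degC) for new test-instrument readings. All models are
#' defined on all finite inputs: spline and polynomial bases evaluate their
#' functional form, isotonic extends its boundary values, tree and boosted
#' models are constant beyond the training range, local regression fits at
#' the query point.
#'
#' @param object A fitted `"calibrator"`.
#' @param newdata Numeric vector of readings, or a data frame with a
#'   `t_test` column.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.calibrator <- function(object, newdata, ...) {
  x <- .as_x(newdata)
  f <- object$fit
  switch(object$spec$model,
    polynomial_huber = {
      xs <- (x - f$center) / f$scale
      drop(outer(xs, 0:f$degree, `^`) %*% f$coef)
    },
    deming = f$intercept + f$slope * x,
    isotonic = {
      if (length(f$knots_x) == 1L) rep(f$knots_y, length(x))
      else stats::approx(f$knots_x, f$knots_y, xout = x, rule = 2)$y
    },
    spline_huber = drop(.spline_basis(x, f$knots) %*% f$coef),
    weighted_spline = drop(.spline_basis(x, f$knots) %*% f$coef),
    loess = vapply(x, .loess_point, numeric(1),
                   x = f$x, y = f$y, rob = f$rob, k = f$k),
    quantile_gbrt = as.numeric(stats::predict(f$models[[2]], .xgb_matrix(x))),
    monotone_boost = as.numeric(stats::predict(f$models[[2]], .xgb_matrix(x))),
    random_forest = stats::predict(f$forest, data.frame(x = x),
                                   num.threads = 1L)$predictions,
    extra_trees = stats::predict(f$forest, data.frame(x = x),
                                 num.threads = 1L)$predictions
  )
}

#' Does a calibrator produce its own quantile intervals?
#' @param spec A `calibrator_spec` or fitted `calibrator`.
#' @return Logical.
#' @export
has_quantile_intervals <- function(spec) {
  model <- if (inherits(spec, "calibrator")) spec$spec$model else spec$model
  model %in% c("quantile_gbrt", "monotone_boost")
}

#' Quantile-model prediction intervals
#'
#' For calibrators with a quantile triplet, returns the 95% interval from the
#' 0.025/0.975 models with quantile crossing repaired by sorting the three
#' outputs per point (so `lower <= point <= upper` always holds).
#'
#' @param object A fitted quantile-capable `"calibrator"`.
#' @param newdata New readings (vector or data frame).
#' @return Tibble with `point`, `lower`, `upper`, `interval_source`,
#'   `extrapolated`.
#' @export
quantile_interval <- function(object, newdata) {
  if (!has_quantile_intervals(object)) {
    stop("calibrator '", object$spec$model,
         "' has no quantile sub-models; use the conformal route", call. = FALSE)
  }
  x <- .as_x(newdata)
  preds <- vapply(object$fit$models,
                  function(m) as.numeric(stats::predict(m, .xgb_matrix(x))),
                  numeric(length(x)))
  preds <- matrix(preds, nrow = length(x))
  sorted <- t(apply(preds, 1L, sort))
  tibble::tibble(
    point = sorted[, 2], lower = sorted[, 1], upper = sorted[, 3],
    interval_source = "quantile_model",
    extrapolated = x < object$x_range[1] | x > object$x_range[2]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.calibrator <- function(x, ...) {
  f <- x$fit
  switch(x$spec$model,
    deming = tibble::tibble(term = c("(Intercept)", "slope"),
                            estimate = c(f$intercept, f$slope)),
    polynomial_huber = tibble::tibble(
      term = paste0("poly", 0:f$degree), estimate = f$coef),
    spline_huber = tibble::tibble(
      term = paste0("ns", seq_along(f$coef) - 1L), estimate = f$coef),
    weighted_spline = tibble::tibble(
      term = paste0("ns", seq_along(f$coef) - 1L), estimate = f$coef),
    isotonic = tibble::tibble(term = paste0("knot", seq_along(f$knots_x)),
                              x = f$knots_x, estimate = f$knots_y),
    tibble::tibble(term = character(), estimate = numeric())
  )
}

#' @export
glance.calibrator <- function(x, ...) {
  tibble::tibble(model = x$spec$model, n = x$n,
                 x_min = x$x_range[1], x_max = x$x_range[2])
}

#' @export
print.calibrator <- function(x, ...) {
  cat(sprintf("<calibrator: %s> trained on n = %d, x in [%.2f, %.2f] degC\n",
              x$spec$model, x$n, x$x_range[1], x$x_range[2]))
  invisible(x)
}
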