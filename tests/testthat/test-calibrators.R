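test_that("robust polynomial: exact fit, outlier resistance, least-squares limit", {
  x <- seq(30, 38, length.out = 40)
  fit <- fit_polynomial_huber(x, 2 * x + 1, degree = 2)
  expect_equal(predict(fit, c(31, 35.5)), 2 * c(31, 35.5) + 1, tolerance = 1e-6)

  # line plus one gross outlier: Huber slope stays near truth, OLS is pulled
  set.seed(10)
  x <- runif(50, 30, 38)
  y <- 1.2 * x - 5 + rnorm(50, 0, 0.1)
  y_out <- y
  y_out[25] <- y[25] + 30
  slope_of <- function(f) (predict(f, 38) - predict(f, 30)) / 8
  clean_slope <- unname(coef(lm(y ~ x))[2])
  hub <- slope_of(fit_polynomial_huber(x, y_out, degree = 1))
  ols <- unname(coef(lm(y_out ~ x))[2])
  expect_lt(abs(hub - clean_slope) / clean_slope, 0.05)
  expect_gt(abs(ols - clean_slope), 3 * abs(hub - clean_slope))

  # all residuals within epsilon * scale => exact least squares
  set.seed(11)
  y2 <- 1.2 * x - 5 + rnorm(50, 0, 0.1)
  f_big_eps <- fit_polynomial_huber(x, y2, degree = 1, epsilon = 100)
  ls <- lm(y2 ~ x)
  expect_equal(predict(f_big_eps, c(30, 38)),
               unname(predict(ls, data.frame(x = c(30, 38)))), tolerance = 1e-6)

  expect_error(fit_polynomial_huber(1:3, 1:3, degree = 2), "degree")
})

test_that("error variance ratio: arithmetic and plug-in recovery", {
  cell <- function(id, r, dev, vals) tibble::tibble(
    participant_id = id, round = r, device = dev,
    replicate = seq_along(vals), temperature_c = vals)
  tab <- dplyr::bind_rows(
    cell("A", "R1", "test", 35 + c(-0.2, 0, 0.2)),
    cell("A", "R1", "reference", 35 + c(-0.1, 0, 0.1)),
    cell("B", "R1", "test", 36 + c(-0.2, 0, 0.2)),
    cell("B", "R1", "reference", 36 + c(-0.1, 0, 0.1))
  )
  expect_equal(estimate_error_variance_ratio(tab), 0.25)
  # equal variances => 1
  tab2 <- tab
  tab2$temperature_c[tab2$device == "reference"] <-
    tab2$temperature_c[tab2$device == "test"]
  expect_equal(estimate_error_variance_ratio(tab2), 1)

  # generated data recovers the configured noise-variance ratio
  cfg <- study_config(n_participants = 200, n_replicates = 15,
                      ref_noise_sd = c(R1 = 0.030, R2 = 0.093),
                      test_noise_sd = c(R1 = 0.340, R2 = 0.300),
                      quantize_to = 0, seed = 12)
  delta <- estimate_error_variance_ratio(generate_study(cfg))
  expected <- mean(c(0.030, 0.093)^2) / mean(c(0.340, 0.300)^2)
  expect_equal(delta, expected, tolerance = 0.15)

  # paired-table input is accepted too
  delta2 <- estimate_error_variance_ratio(pair_replicates(generate_study(cfg)))
  expect_equal(delta2, delta, tolerance = 1e-12)
})

test_that("Deming regression: exact line, symmetry, delta limits", {
  x <- c(30, 32, 34, 36, 38)
  y <- 0.8 * x + 5
  for (d in c(0.1, 1, 10)) {
    f <- fit_deming(x, y, delta = d)
    expect_equal(f$fit$slope, 0.8, tolerance = 1e-10)
    expect_equal(f$fit$intercept, 5, tolerance = 1e-8)
  }

  set.seed(13)
  xs <- rnorm(200); ys <- xs + rnorm(200)
  fxy <- fit_deming(xs, ys, delta = 1)
  fyx <- fit_deming(ys, xs, delta = 1)
  expect_equal(fxy$fit$slope, 1 / fyx$fit$slope, tolerance = 1e-10)

  # delta -> Inf: ordinary regression of y on x; delta -> 0: inverse of x on y
  ols_yx <- unname(coef(lm(ys ~ xs))[2])
  inv_xy <- 1 / unname(coef(lm(xs ~ ys))[2])
  expect_equal(fit_deming(xs, ys, delta = 1e6)$fit$slope, ols_yx,
               tolerance = 1e-4)
  expect_equal(fit_deming(xs, ys, delta = 1e-6)$fit$slope, inv_xy,
               tolerance = 1e-4)

  # centroid property
  expect_equal(predict(fxy, mean(xs)), mean(ys), tolerance = 1e-10)
  expect_error(fit_deming(c(1, 2, 3), c(1, 1, 1), delta = 1), "covariance")
})

test_that("Deming corrects errors-in-x attenuation", {
  set.seed(14)
  n <- 4000
  xi <- rnorm(n, 35, 2)           # latent truth, slope 1
  x <- xi + rnorm(n, 0, 0.34)     # predictor with error
  y <- xi + rnorm(n, 0, 0.03)
  delta <- 0.03^2 / 0.34^2
  ols <- unname(coef(lm(y ~ x))[2])
  dem <- fit_deming(x, y, delta)$fit$slope
  atten <- 4 / (4 + 0.34^2)
  expect_equal(ols, atten, tolerance = 0.02)
  expect_equal(dem, 1, tolerance = 0.02)
  expect_gt(dem, ols)
})

test_that("PAVA: worked examples and brute-force equivalence battery", {
  expect_equal(pava(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(pava(c(1, 3, 2)), c(1, 2.5, 2.5))
  expect_equal(pava(c(3, 2, 1)), rep(2, 3))
  # weighted total pooling
  expect_equal(pava(c(3, 1), w = c(3, 1)), rep(2.5, 2))

  set.seed(15)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    y <- round(rnorm(n), 2)
    w <- sample(1:4, n, replace = TRUE)
    expect_equal(pava(y, w), brute_force_isotonic(y, w), tolerance = 1e-10)
  }
})

test_that("isotonic calibrator: interpolation, boundary extension, tie handling", {
  f <- fit_isotonic(c(1, 2, 3), c(1, 3, 2))
  expect_equal(predict(f, c(1, 2, 3)), c(1, 2.5, 2.5))
  # linear interpolation between knots, constant beyond the range
  expect_equal(predict(f, 1.5), 1.75)
  expect_equal(predict(f, c(-5, 10)), c(1, 2.5))
  # monotone y reproduced exactly
  f2 <- fit_isotonic(1:5, c(1, 2, 4, 8, 16))
  expect_equal(predict(f2, 1:5), c(1, 2, 4, 8, 16))
  # ties in x collapse to one knot
  f3 <- fit_isotonic(c(1, 1, 2), c(0, 2, 3))
  expect_equal(predict(f3, 1), 1)
})

test_that("Huber spline: contains linear functions and resists outliers", {
  set.seed(16)
  x <- runif(60, 30, 38)
  y <- 1.5 * x - 10
  f <- fit_spline_huber(x, y)
  grid <- seq(30.5, 37.5, length.out = 9)
  expect_equal(predict(f, grid), 1.5 * grid - 10, tolerance = 1e-6)

  y_noise <- y + rnorm(60, 0, 0.1)
  y_out <- y_noise
  y_out[30] <- y_out[30] + 25
  f_clean <- fit_spline_huber(x, y_noise)
  f_out <- fit_spline_huber(x, y_out)
  at <- x[30]
  expect_lt(abs(predict(f_out, at) - predict(f_clean, at)) /
              abs(predict(f_clean, at)), 0.05)
})

test_that("local regression: constant data, global-OLS limit, robustness weights", {
  set.seed(17)
  x <- runif(40, 30, 38)
  f_const <- fit_loess_robust(x, rep(2, 40), frac = 0.5, robust_iters = 1)
  expect_equal(predict(f_const, c(31, 35)), c(2, 2), tolerance = 1e-10)

  # exactly linear response: every weighted local fit, and hence the
  # frac = 1 fit, reproduces the global least-squares line
  y_lin <- 0.7 * x + 3
  f_global <- fit_loess_robust(x, y_lin, frac = 1, robust_iters = 0)
  ols <- lm(y_lin ~ x)
  grid <- c(30, 34, 38)
  expect_equal(predict(f_global, grid),
               unname(predict(ols, data.frame(x = grid))), tolerance = 1e-8)
  # with noise, the local fit tracks the line to within the noise scale
  y <- 0.7 * x + 3 + rnorm(40, 0, 0.5)
  f_noisy <- fit_loess_robust(x, y, frac = 1, robust_iters = 1)
  expect_lt(max(abs(predict(f_noisy, grid) - (0.7 * grid + 3))), 1)

  expect_error(fit_loess_robust(x, y, frac = 0.01), "frac")
})

test_that("weighted spline: homoscedastic equivalence and two-regime weights", {
  set.seed(18)
  x <- runif(100, 30, 38)
  y <- 0.9 * x + rnorm(100, 0, 0.2)
  fw <- fit_weighted_spline(x, y, n_knots = 4, n_bins = 5)
  # unweighted natural-spline fit as oracle
  knots <- unname(quantile(x, probs = seq(0, 1, length.out = 4)))
  basis <- splines::ns(x, knots = knots[2:3], Boundary.knots = knots[c(1, 4)])
  un <- lm(y ~ basis)
  grid <- seq(31, 37, length.out = 13)
  gbasis <- splines::ns(grid, knots = knots[2:3], Boundary.knots = knots[c(1, 4)])
  expect_equal(predict(fw, grid),
               unname(cbind(1, gbasis) %*% coef(un))[, 1], tolerance = 0.1)

  # heteroscedastic: low-noise half gets ~(sd ratio)^2 larger weight
  x2 <- c(runif(100, 30, 34), runif(100, 34.0001, 38))
  y2 <- x2 + rnorm(200, 0, rep(c(0.1, 1), each = 100))
  f2 <- fit_weighted_spline(x2, y2, n_knots = 4, n_bins = 4)
  v <- f2$fit$bin_var
  expect_gt(mean(v[3:4]) / mean(v[1:2]), 20)

  expect_warning(fit_weighted_spline(runif(10, 30, 38), rnorm(10), n_bins = 10),
                 "reduced")
})

test_that("quantile boosting: pinball triplet, ordering, and approximate median", {
  set.seed(19)
  n <- 2000
  x <- runif(n, 30, 38)
  y <- x + rnorm(n, 0, 0.5)
  f <- fit_quantile_boost(x, y, n_estimators = 150, seed = 1)
  grid <- seq(30.5, 37.5, length.out = 101)
  iv <- quantile_interval(f, grid)
  expect_true(all(iv$lower <= iv$point & iv$point <= iv$upper))
  # median model tracks the identity within noise
  expect_lt(max(abs(iv$point - grid)), 0.5)
  expect_error(fit_quantile_boost(x, y, quantiles = c(0, 0.5, 1)), "quantiles")
  expect_error(fit_quantile_boost(1:5, 1:5), "n >= 20")
})

test_that("monotone boosted median: hard monotonicity and near-interpolation", {
  set.seed(20)
  x <- runif(500, 30, 38)
  y <- x + rnorm(500, 0, 0.3)
  f <- fit_monotone_boost(x, y, n_estimators = 300, seed = 1)
  grid <- seq(29, 39, length.out = 400)
  p <- predict(f, grid)
  expect_true(all(diff(p) >= -1e-9))

  # monotone noiseless response: constraint inactive, near-interpolation
  xm <- seq(30, 38, length.out = 100)
  fm <- fit_monotone_boost(xm, 2 * xm, n_estimators = 400,
                           learning_rate = 0.1, seed = 1)
  expect_lt(mean(abs(predict(fm, xm) - 2 * xm)), 0.25)
  iv <- quantile_interval(fm, c(31, 35))
  expect_true(all(iv$lower <= iv$point & iv$point <= iv$upper))
})

test_that("tree ensembles: constant fit, memorisation, range contract", {
  set.seed(21)
  x <- runif(50, 30, 38)
  for (kind in c("random_forest", "extra_trees")) {
    f <- fit_tree_ensemble(x, rep(36.5, 50), kind, n_estimators = 50, seed = 1)
    expect_equal(predict(f, c(31, 44)), c(36.5, 36.5))
  }
  xg <- seq(30, 38, length.out = 200)
  f2 <- fit_tree_ensemble(xg, xg, "extra_trees", n_estimators = 100,
                          min_samples_leaf = 1, seed = 1)
  expect_lt(mean(abs(predict(f2, xg) - xg)), 0.1)
  # predictions stay within the training response range
  set.seed(22)
  yr <- rnorm(200, 35, 1)
  f3 <- fit_tree_ensemble(xg, yr, "random_forest", n_estimators = 100, seed = 1)
  p <- predict(f3, seq(25, 43, length.out = 50))
  expect_true(all(p >= min(yr) & p <= max(yr)))
})

test_that("fit_calibrator dispatch and spec validation", {
  set.seed(23)
  x <- runif(80, 30, 38)
  y <- x - 1.4 + rnorm(80, 0, 0.3)
  for (m in names(default_calibrator_specs())) {
    spec <- calibrator_spec(m, seed = 1)
    if (m %in% c("quantile_gbrt", "monotone_boost")) {
      spec$params$n_estimators <- 50L
    }
    f <- fit_calibrator(spec, x, y, delta = if (m == "deming") 0.1)
    expect_s3_class(f, "calibrator")
    p <- predict(f, c(31, 34, 37))
    expect_true(all(is.finite(p)))
    expect_equal(glance(f)$model, m)
  }
  expect_error(calibrator_spec("polynomial_huber", nope = 1), "unknown hyper")
  expect_error(calibrator_spec("unheard_of"), "arg")
  expect_error(fit_calibrator(calibrator_spec("deming"), x, y), "delta")
})

test_that("quantile intervals are refused for point estimators", {
  f <- fit_isotonic(1:10, 1:10)
  expect_error(quantile_interval(f, 5), "conformal")
  expect_false(has_quantile_intervals(f))
  expect_true(has_quantile_intervals(calibrator_spec("quantile_gbrt")))
})
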