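test_that("density and stiffness maps pair by physical position", {
  dm <- tibble::tibble(
    stack_id = rep(1:4, each = 4),
    x_mm = rep(c(0, 0.5, 1, 1.5), each = 4) + rep(c(-0.05, -0.05, 0.05, 0.05), 4),
    y_mm = rep(c(-0.05, 0.05, -0.05, 0.05), 4),
    density = rep(c(100, 600, 1200, 2000), each = 4) + rep(c(-5, 0, 5, 0), 4))
  sm <- tibble::tibble(x_mm = c(0, 0.5, 1, 1.5), y_mm = 0,
                       stiffness_kpa = c(1, 3, 6, 9), sem_kpa = 0.2)

  pts <- pair_measurements(dm, sm, tolerance_mm = 0.3)
  expect_equal(nrow(pts), 4)
  expect_true(all(pts$offset_mm < 1e-9))   # stack centers coincide
  expect_equal(pts$density_mean, c(100, 600, 1200, 2000))
  expect_true(all(pts$density_sem > 0))

  # offset grid within tolerance: full pairing with reported offsets
  sm_off <- dplyr::mutate(sm, x_mm = .data$x_mm + 0.1)
  pts_off <- pair_measurements(dm, sm_off, tolerance_mm = 0.3)
  expect_equal(nrow(pts_off), 4)
  expect_equal(pts_off$offset_mm, rep(0.1, 4), tolerance = 1e-9)

  # zero tolerance on offset grids: pairing error
  expect_error(pair_measurements(dm, sm_off, tolerance_mm = 0),
               class = "gradgel_pairing_error")
})

test_that("linear calibration recovers exact and noisy generators", {
  pts <- sim_gradient(linear_truth(), linear_design())
  m <- fit_linear_calibration(pts)
  expect_equal(m$coef[["a"]], 0.0044, tolerance = 1e-12)
  expect_equal(m$coef[["b"]], 0.903, tolerance = 1e-10)

  # three collinear points give the interpolating line
  tri <- tibble::tibble(density = c(0, 1000, 2000), stiffness = c(1, 3, 5))
  m3 <- fit_linear_calibration(tri)
  expect_equal(unname(m3$coef), c(0.002, 1), tolerance = 1e-12)

  expect_error(fit_linear_calibration(
    tibble::tibble(density = c(5, 5, 5), stiffness = 1:3)),
    class = "gradgel_fit_error")

  # mean parameter bias under the study conditions (n=20, noise 10% of
  # range, 200 replicates): consistent with < 5% of truth, allowing the
  # Monte-Carlo standard error of the mean
  yr <- stiffness_range(linear_truth(), linear_design())
  est <- t(vapply(1:200, function(r) {
    unname(fit_linear_calibration(
      sim_gradient(linear_truth(), linear_design(),
                   stiffness_noise_sd = 0.1 * yr, seed = r))$coef)
  }, c(1, 1)))
  truth <- c(0.0044, 0.903)
  bias <- colMeans(est) - truth
  se_mc <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(bias) <= 0.05 * abs(truth) + 3 * se_mc))
})

test_that("logit calibration round-trips the published constants", {
  pts <- sim_gradient(logit_truth(), logit_design())
  m <- fit_logit_calibration(pts)
  expect_true(all(abs(m$coef - logit_truth()$coef) /
                    abs(logit_truth()$coef) < 1e-4))

  # symmetry: prediction at the abscissa midpoint is exactly y_half
  mid <- (m$coef[["x_lo"]] + m$coef[["x_hi"]]) / 2
  expect_equal(predict(m, mid)$stiffness_kpa, m$coef[["y_half"]],
               tolerance = 1e-9)

  expect_error(fit_logit_calibration(pts[1:4, ]), class = "gradgel_fit_error")

  # fitted curve is strictly increasing over its domain
  grid <- seq(min(pts$density_mean), max(pts$density_mean), length.out = 100)
  expect_true(all(diff(predict(m, grid)$stiffness_kpa) > 0))

  # inversion is the exact inverse on (x_lo, x_hi)
  dens <- seq(600, 4100, length.out = 9)
  expect_equal(invert_calibration(m, predict(m, dens)$stiffness_kpa), dens,
               tolerance = 1e-8)

  # robust parameter recovery at the study conditions: median error < 5%
  # of truth for y_half and rate, < 5% of the abscissa span for the limits
  # (the limit estimators are heavy-tailed at this noise level, so medians,
  # not means, are the stable location statistic)
  yr <- stiffness_range(logit_truth(), logit_design())
  est <- matrix(NA_real_, 100, 4)
  for (r in 1:100) {
    mm <- tryCatch(fit_logit_calibration(
      sim_gradient(logit_truth(), logit_design(),
                   stiffness_noise_sd = 0.1 * yr, seed = r)),
      error = function(e) NULL)
    if (!is.null(mm)) est[r, ] <- mm$coef
  }
  expect_gt(sum(!is.na(est[, 1])), 90)
  med <- apply(est, 2, median, na.rm = TRUE)
  truth <- logit_truth()$coef
  span <- truth[["x_hi"]] - truth[["x_lo"]]
  expect_lt(abs(med[1] - truth[["y_half"]]) / truth[["y_half"]], 0.05)
  expect_lt(abs(med[2] - truth[["rate"]]) / truth[["rate"]], 0.05)
  expect_lt(abs(med[3] - truth[["x_lo"]]) / span, 0.05)
  expect_lt(abs(med[4] - truth[["x_hi"]]) / span, 0.05)
})

test_that("prediction bands behave like OLS/delta-method bands should", {
  m <- calibration_model("linear", c(a = 0.0044, b = 0.903))
  pr <- predict(m, c(0, 1000))
  expect_equal(pr$stiffness_kpa, c(0.903, 5.303))
  # zero covariance, zero sigma: band collapses onto the curve
  expect_equal(pr$ci_low, pr$stiffness_kpa)
  expect_equal(pr$ci_high, pr$stiffness_kpa)

  # fitted model: CI narrowest at the density centroid, growing outward
  pts <- sim_gradient(linear_truth(), linear_design(),
                      stiffness_noise_sd = 0.8, seed = 42)
  mf <- fit_linear_calibration(pts)
  xbar <- mean(pts$density_mean)
  grid <- seq(0, 4000, length.out = 81)
  w <- predict(mf, grid)
  width <- w$ci_high - w$ci_low
  expect_equal(grid[which.min(width)], grid[which.min(abs(grid - xbar))])
  expect_true(all(diff(width[grid >= xbar]) > 0))
  expect_true(all(diff(width[grid <= xbar]) < 0))

  # logit domain: stiffness undefined outside (x_lo, x_hi)
  lg <- logit_truth()
  expect_error(predict(lg, 5000), class = "gradgel_domain_error")
  expect_error(predict(lg, -200), class = "gradgel_domain_error")

  # extrapolation is flagged for the linear family
  expect_true(predict(mf, 5500)$extrapolated)
  expect_false(predict(mf, 1500)$extrapolated)
})

test_that("validation flags points against the band", {
  pts <- sim_gradient(linear_truth(), linear_design(),
                      stiffness_noise_sd = 0.8, seed = 7)
  m <- fit_linear_calibration(pts)

  on_curve <- predict(m, 1200)$stiffness_kpa
  v1 <- validate_calibration(m, tibble::tibble(density = 1200,
                                               stiffness = on_curve))
  expect_true(v1$inside)

  half <- (v1$ci_high - v1$ci_low) / 2
  v2 <- validate_calibration(m, tibble::tibble(
    density = 1200, stiffness = on_curve + 10 * half))
  expect_false(v2$inside)
  expect_equal(glance(v2)$fraction_within, 0)

  expect_error(validate_calibration(m, tibble::tibble(density = numeric(),
                                                      stiffness = numeric())),
               class = "gradgel_input_error")
})

test_that("model selection picks the generating family", {
  lin_pts <- sim_gradient(linear_truth(), linear_design(),
                          stiffness_noise_sd = 0.4, seed = 5)
  expect_equal(select_calibration(lin_pts)$kind, "linear")

  yr <- stiffness_range(logit_truth(), logit_design())
  log_pts <- sim_gradient(logit_truth(), logit_design(),
                          stiffness_noise_sd = 0.02 * yr, seed = 6)
  expect_equal(select_calibration(log_pts)$kind, "logit")

  # the near-tie flag mirrors the margin threshold
  expect_warning(sel <- select_calibration(lin_pts, warn_margin = Inf),
                 "tied")
  expect_true(sel$near_tie)
})

test_that("calibration files round-trip and reject unknown kinds", {
  pts <- sim_gradient(logit_truth(), logit_design(),
                      stiffness_noise_sd = 1, seed = 3)
  m <- fit_logit_calibration(pts)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(m, path)
  back <- read_calibration(path)
  expect_equal(back$coef, m$coef)
  expect_equal(back$vcov, m$vcov)
  expect_equal(back$sigma, m$sigma)
  expect_equal(tidy(back), tidy(m))
  expect_equal(predict(back, 2000), predict(m, 2000))

  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "gradgel-calibration", kind = "spline",
                            params = list(a = 1)), bad, auto_unbox = TRUE)
  expect_error(read_calibration(bad), class = "gradgel_parse_error")
})
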