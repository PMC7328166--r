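test_that("nuclear-to-cytoplasmic ratio matches constructed phantoms", {
  ph <- sim_cell_phantom(nucleus_intensity = 200, cytoplasm_intensity = 100)

  # uniform signal: ratio is exactly 1
  uni <- matrix(37, nrow(ph$signal_channel), ncol(ph$signal_channel))
  expect_equal(nc_ratio(uni, ph$nucleus_mask, ph$pixel_size_um)$nc_ratio, 1)

  # nucleus 200 / 1-um ring inside 100-cytoplasm: exactly 2
  r <- nc_ratio(ph$signal_channel, ph$nucleus_mask, ph$pixel_size_um)
  expect_equal(r$nc_ratio, 2)
  expect_false(r$flagged)

  # intensity-scale invariance
  r7 <- nc_ratio(7 * ph$signal_channel, ph$nucleus_mask, ph$pixel_size_um)
  expect_equal(r7$nc_ratio, r$nc_ratio)

  # 3D input is projected first
  stack <- array(0, dim = c(dim(ph$signal_channel), 2))
  stack[, , 1] <- ph$signal_channel / 2
  stack[, , 2] <- ph$signal_channel
  expect_equal(nc_ratio(stack, ph$nucleus_mask, ph$pixel_size_um)$nc_ratio, 2)

  # nucleus at the border: flagged, not dropped
  m <- matrix(FALSE, 40, 40); m[1:10, 1:10] <- TRUE
  rb <- nc_ratio(matrix(1, 40, 40), m, pixel_size_um = 0.5)
  expect_true(rb$flagged)
})

test_that("cell shape gives analytic areas and roundness", {
  ph <- sim_cell_phantom(nucleus_radius_um = 8, cell_axes_um = c(20, 12))

  disc <- cell_shape(ph$nucleus_mask, ph$pixel_size_um)
  expect_equal(disc$area_um2, pi * 64, tolerance = 0.02)
  expect_equal(disc$roundness, 1, tolerance = 0.02)

  # 20 x 12 half-axes: roundness = b/a = 0.6
  ell <- cell_shape(ph$cell_mask, ph$pixel_size_um)
  expect_equal(ell$area_um2, pi * 20 * 12, tolerance = 0.02)
  expect_equal(ell$roundness, 0.6, tolerance = 0.02)

  # 2:1 ellipse: roundness 0.5
  ph2 <- sim_cell_phantom(cell_axes_um = c(16, 8))
  expect_equal(cell_shape(ph2$cell_mask, ph2$pixel_size_um)$roundness, 0.5,
               tolerance = 0.02)

  # single pixel: degenerate, flagged
  one <- matrix(FALSE, 10, 10); one[5, 5] <- TRUE
  expect_true(cell_shape(one, 0.5)$flagged)

  # translation invariance of roundness
  m1 <- matrix(FALSE, 60, 60); m2 <- m1
  xs <- (1:60 - 20)^2
  m1[outer(xs, xs, "+") <= 100] <- TRUE
  ys <- (1:60 - 35)^2
  m2[outer(ys, ys, "+") <= 100] <- TRUE
  expect_equal(cell_shape(m1, 1)$roundness, cell_shape(m2, 1)$roundness)
})

test_that("adhesion lengths recover synthetic bars", {
  img <- bar_image(length_um = 3.5, width_um = 0.5, angle_deg = 0)
  got <- adhesion_lengths(img, 0.08, threshold = 10)
  expect_equal(nrow(got), 1)
  expect_lt(abs(got$length_um - 3.5) / 3.5, 0.1)

  # rotation leaves the measured length unchanged up to discretization
  for (ang in c(20, 45, 75)) {
    rot <- adhesion_lengths(bar_image(angle_deg = ang), 0.08, threshold = 10)
    expect_lt(abs(rot$length_um - got$length_um) / got$length_um, 0.1)
  }

  # blank image: empty result with a warning
  expect_warning(none <- adhesion_lengths(matrix(0, 50, 50), 0.1),
                 class = "gradgel_empty_mask")
  expect_equal(nrow(none), 0)

  # component count is monotone non-increasing in the size filter
  adh <- tibble::tibble(
    x_um = c(5, 12, 18), y_um = c(5, 12, 18),
    length_um = c(0.6, 2, 4), width_um = c(0.4, 0.5, 0.5),
    angle_deg = c(0, 30, 100), intensity_a = 100, intensity_b = 0)
  multi <- sim_adhesion_pair(adh, image_size_um = 24,
                             pixel_size_um = 0.08)$channel_a
  counts <- vapply(c(1, 20, 120, 1500), function(ms) {
    nrow(suppressWarnings(
      adhesion_lengths(multi, 0.08, threshold = 10, min_area_px = ms)))
  }, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("length-stiffness model recovers and prefers the log form", {
  # exact recovery on noise-free logarithmic data
  E <- seq(0.5, 22, length.out = 40)
  rec <- tibble::tibble(stiffness_kpa = E, length_um = 1.2 + 0.55 * log(E))
  fit <- fit_length_stiffness(rec)
  expect_equal(fit$alpha, 1.2, tolerance = 1e-10)
  expect_equal(fit$beta, 0.55, tolerance = 1e-10)
  expect_equal(fit$preferred, "logarithmic")

  # steep-then-plateau data prefers log over linear by AICc
  set.seed(31)
  noisy <- tibble::tibble(stiffness_kpa = E,
                          length_um = 1.2 + 0.55 * log(E) + rnorm(40, 0, 0.1))
  expect_equal(fit_length_stiffness(noisy)$preferred, "logarithmic")

  expect_error(fit_length_stiffness(
    tibble::tibble(stiffness_kpa = rep(5, 10), length_um = runif(10))),
    class = "gradgel_fit_error")
  expect_error(fit_length_stiffness(
    tibble::tibble(stiffness_kpa = c(-1, 1, 2, 5, 9), length_um = 1:5)),
    class = "gradgel_input_error")
})

test_that("records pick up calibrated stiffness at their tile", {
  dm <- tibble::tibble(x_mm = rep(c(0, 0.1, 0.2), each = 2),
                       y_mm = rep(c(0, 0.1), 3),
                       density = c(0, 0, 1000, 1000, 2500, 2500))
  attr(dm, "tile_size_um") <- c(100, 100)
  m <- calibration_model("linear", c(a = 0.0044, b = 0.903))
  rec <- tibble::tibble(x_mm = c(0.001, 0.002, 0.101, 5),
                        y_mm = c(0.001, 0.002, 0.001, 5))
  out <- attach_stiffness(rec, dm, m)
  expect_equal(out$stiffness_kpa[1], 0.903)     # density 0 tile
  expect_equal(out$stiffness_kpa[1], out$stiffness_kpa[2])  # same tile
  expect_equal(out$stiffness_kpa[3], 0.0044 * 1000 + 0.903)
  expect_true(out$outside_map[4])
  expect_true(is.na(out$stiffness_kpa[4]))
})
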