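test_that("bead phantom renders the requested Poisson process", {
  # zero density: background-only stack, no beads
  st0 <- sim_bead_stack(field_size_um = c(20, 20, 4),
                        voxel_size_um = c(0.5, 0.5, 1),
                        density = 0, background = 10, noise_sd = 2, seed = 1)
  expect_equal(nrow(st0$beads), 0)
  expect_true(all(abs(st0$intensities - 10) < 20))  # noise around background

  # Poisson mean: bead count over 100 seeds within 3 standard errors of
  # density * area (20 per 10^4 um^2 on a 10^4 um^2 field -> lambda = 20)
  counts <- vapply(1:100, function(s) {
    nrow(sim_bead_stack(field_size_um = c(100, 100, 2),
                        voxel_size_um = c(1, 1, 1), density = 20,
                        noise_sd = 0, background = 0, seed = s)$beads)
  }, 1)
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 100))

  # determinism under a fixed seed
  a <- small_phantom(seed = 11)
  b <- small_phantom(seed = 11)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$beads, b$beads)

  # configuration errors
  expect_error(sim_bead_stack(field_size_um = c(10, 10, 3),
                              voxel_size_um = c(3, 3, 1)),
               class = "gradgel_config_error")
  expect_error(sim_bead_stack(voxel_size_um = c(0, 1, 1)),
               class = "gradgel_config_error")
})

test_that("Hertz forward model matches hand arithmetic and its symmetries", {
  # hand oracle: E=10 kPa, R=5 um, nu=0.5, delta=1 um
  # F = (4/3) * (10 / 0.75) * sqrt(5) * 1 = 39.7523196 nN
  expect_equal(hertz_force(1, 10, 5, 0.5), 39.7523196, tolerance = 1e-8)
  expect_equal(hertz_force(0, 10, 5, 0.5), 0)
  expect_equal(hertz_force(-0.3, 10, 5, 0.5), 0)  # pre-contact

  # linear in E, strictly increasing in delta
  d <- seq(0.05, 1, by = 0.05)
  expect_equal(hertz_force(d, 20, 5, 0.5), 2 * hertz_force(d, 10, 5, 0.5))
  for (E in c(0.5, 4, 60)) {
    f <- hertz_force(d, E, 5, 0.45)
    expect_true(all(diff(f) > 0))
  }
})

test_that("simulated force curves honour the contact point and validity", {
  cv <- sim_force_curve(10, contact_um = 2, max_indentation_um = 1,
                        n_points = 100, noise_sd_nn = 0)
  pre <- cv$position_um <= 2
  expect_true(all(cv$force_nN[pre] == 0))
  expect_true(all(cv$force_nN[!pre] > 0))
  expect_true(all(diff(cv$position_um) > 0))

  # doubling E doubles every post-contact force (same seed, noise-free)
  cv2 <- sim_force_curve(20, contact_um = 2, max_indentation_um = 1,
                         n_points = 100, noise_sd_nn = 0)
  expect_equal(cv2$force_nN, 2 * cv$force_nN)

  expect_error(sim_force_curve(10, tip_radius_um = 5, max_indentation_um = 6),
               class = "gradgel_config_error")
  expect_error(sim_force_curve(10, poisson_ratio = 0.7),
               class = "gradgel_config_error")
})

test_that("gradient generator reproduces its calibration truth", {
  # noise-free linear: printed constants, densities 0..4000 span ~0.9-18.5
  pts <- sim_gradient(linear_truth(), linear_design())
  expect_equal(range(pts$stiffness_mean), c(0.903, 18.503), tolerance = 1e-12)
  refit <- fit_linear_calibration(pts)
  expect_equal(unname(refit$coef), c(0.0044, 0.903), tolerance = 1e-10)

  # fixed-seed reproducibility with noise
  n1 <- sim_gradient(linear_truth(), linear_design(),
                     stiffness_noise_sd = 1, seed = 5)
  n2 <- sim_gradient(linear_truth(), linear_design(),
                     stiffness_noise_sd = 1, seed = 5)
  expect_identical(n1$stiffness_mean, n2$stiffness_mean)
})

test_that("adhesion and cell phantoms carry their ground truth", {
  adh <- tibble::tibble(x_um = 10, y_um = 10, length_um = 3, width_um = 0.5,
                        angle_deg = 0, intensity_a = 80, intensity_b = 0)
  p <- sim_adhesion_pair(adh, image_size_um = 20, pixel_size_um = 0.1)
  expect_true(any(p$mask_a))
  expect_false(any(p$mask_b))   # rendered in channel A only
  expect_true(all(p$channel_b == 0))

  ph <- sim_cell_phantom(nucleus_intensity = 200, cytoplasm_intensity = 100)
  expect_true(all(ph$signal_channel[ph$nucleus_mask] == 200))
  ring <- ph$cell_mask & !ph$nucleus_mask
  expect_true(all(ph$signal_channel[ring] == 100))
})
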