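test_that("max projection keeps the brightest slice per pixel", {
  one <- array(runif(64), dim = c(8, 8, 1))
  expect_equal(max_project(one), one[, , 1])

  two <- array(0, dim = c(8, 8, 2))
  two[, , 1] <- runif(64)
  two[, , 2] <- two[, , 1] + 1          # second slice everywhere brighter
  expect_equal(max_project(two), two[, , 2])

  expect_error(max_project(array(0, c(0, 0, 0))), class = "gradgel_error")

  # every ground-truth bead position coincides with a local maximum of the
  # projection: the brightest pixel within 2 px of the bead dominates its
  # 9 x 9 neighbourhood
  st <- small_phantom(density = 15, seed = 3)
  proj <- max_project(st)
  px <- st$voxel_size_um[1]
  for (b in seq_len(nrow(st$beads))) {
    i <- round(st$beads$x_um[b] / px + 0.5)
    j <- round(st$beads$y_um[b] / px + 0.5)
    near <- proj[max(1, i - 2):min(nrow(proj), i + 2),
                 max(1, j - 2):min(ncol(proj), j + 2)]
    wide <- proj[max(1, i - 4):min(nrow(proj), i + 4),
                 max(1, j - 4):min(ncol(proj), j + 4)]
    expect_equal(max(near), max(wide))
  }
})

test_that("tile splitting is exact, conservative and reversible", {
  img <- matrix(rnorm(24 * 36), 24, 36)
  tiles <- split_tiles(img, c(2, 3))
  expect_length(tiles, 6)
  expect_equal(sum(vapply(tiles, sum, 1)), sum(img))  # pixel conservation

  # reassembly is the identity
  back <- matrix(0, 24, 36)
  for (t in tiles) {
    off <- attr(t, "offset_px")
    back[off[1] + seq_len(nrow(t)), off[2] + seq_len(ncol(t))] <- t
  }
  expect_identical(back, img)

  expect_identical(split_tiles(img, c(1, 1))[[1]][, ], img)  # 1x1 identity
  expect_error(split_tiles(matrix(0, 7, 8), c(2, 2)),
               class = "gradgel_shape_error")
  padded <- split_tiles(matrix(1, 7, 8), c(2, 2), pad = TRUE)
  expect_length(padded, 4)
  expect_equal(sum(vapply(padded, sum, 1)), 56)  # zero padding adds nothing
})

test_that("bead counting recovers phantom ground truth", {
  blank <- matrix(0, 32, 32)
  expect_equal(count_beads(blank)$count, 0)

  st <- small_phantom(density = 20, seed = 7)
  got <- count_beads(max_project(st))
  expect_equal(got$count, nrow(st$beads))

  # with overlaps and noise: within 3 sqrt(N) of truth, per seed
  for (s in 1:25) {
    stn <- small_phantom(density = 40, seed = s, noise_sd = 2,
                         background = 10)
    est <- count_beads(max_project(stn))$count
    N <- nrow(stn$beads)
    expect_lt(abs(est - N), 3 * sqrt(max(N, 1)) + 1)
  }
})

test_that("density map converts counts to beads per 10^4 um^2", {
  st <- small_phantom(density = 20, seed = 7)
  dm <- bead_density_map(st, grid = c(1, 1))
  # 100 x 100 um tile: density equals the count itself
  expect_equal(dm$density, dm$n_beads)
  expect_equal(dm$tile_area_um2, 1e4)

  # all-blank mosaic -> all-zero matrix
  blank <- small_phantom(density = 0, seed = 1)
  dmb <- bead_density_map(blank, grid = c(2, 2), threshold = 1)
  expect_equal(nrow(dmb), 4)
  expect_true(all(dmb$density == 0))

  # density is invariant under intensity rescaling with the relative threshold
  proj <- max_project(st)
  expect_equal(count_beads(proj)$count, count_beads(proj * 13.7)$count)
})

test_that("doubling the phantom density doubles the estimate", {
  est <- function(dens) {
    mean(vapply(1:50, function(s) {
      count_beads(max_project(small_phantom(density = dens, seed = s,
                                            noise_sd = 2,
                                            background = 10)))$count
    }, 1))
  }
  e1 <- est(15); e2 <- est(30)
  # ratio within sampling error of 2 (SE of each mean ~ sqrt(dens/50))
  expect_lt(abs(e2 / e1 - 2), 0.25)
})

test_that("a linear density ramp is recovered across the mosaic", {
  # 4-stack strip with increasing density; fitted slope of density vs x
  # should match the generator ramp
  dens_true <- c(5, 15, 25, 35)
  stacks <- lapply(seq_along(dens_true), function(i) {
    sim_bead_stack(field_size_um = c(100, 100, 4),
                   voxel_size_um = c(0.5, 0.5, 1), density = dens_true[i],
                   noise_sd = 1, background = 5, seed = 100 + i,
                   origin_mm = c((i - 1) * 0.1, 0))
  })
  dm <- bead_density_map(stacks, grid = c(2, 2))
  expect_equal(nrow(dm), 16)
  agg <- dplyr::summarise(dplyr::group_by(dm, .data$stack_id),
                          x = mean(.data$x_mm), d = mean(.data$density))
  fit <- lm(d ~ x, data = agg)
  # generator slope: 10 density units per 0.1 mm = 100 per mm
  expect_equal(unname(coef(fit)[2]), 100, tolerance = 0.3)
})
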