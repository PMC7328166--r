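# Synthetic fixtures: bead-phantom image stacks, Hertz forward-model force
# curves, paired density/stiffness gradient fields, two-channel adhesion
# images and nucleus/cytoplasm phantom cells. Every generator is
# deterministic under a fixed seed. These are first-class, tested inputs for
# the rest of the pipeline, not throwaway test helpers.

#' Simulate a 3D image stack of fluorescent beads
#'
#' Renders a spatial Poisson process of sub-resolution beads as Gaussian
#' blobs in a 3D intensity stack, emulating a confocal stack of a
#' bead-embedded polyacrylamide gel. The expected number of beads in any
#' region follows `density` (beads per 10^4 µm²) times its area; bead
#' positions are uniform within the field (or thinned against a spatially
#' varying density function), and each bead adds a Gaussian blob of width
#' `psf_sigma_um`.
#'
#' @param field_size_um Physical extent, µm, as `c(x, y, z)`. Must be an
#'   integer multiple of `voxel_size_um` along each axis.
#' @param voxel_size_um Voxel size, µm, as `c(x, y, z)`; all > 0.
#' @param density Expected bead density in beads per 10^4 µm² of projected
#'   (x, y) area: a single non-negative number, or a function `f(x_um, y_um)`
#'   (vectorised) for a spatially varying field.
#' @param psf_sigma_um Gaussian blob sigma, µm (lateral and axial alike).
#' @param amplitude Peak intensity added by one bead.
#' @param background Constant background intensity.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param origin_mm Physical position, mm, of the (x, y) corner of the first
#'   voxel (used when assembling mosaics of stacks).
#'
#' @return A list of class `bead_stack`: `intensities` (3D array, x–y–z),
#'   `beads` (tibble of ground-truth positions `x_um`, `y_um`, `z_um`),
#'   `voxel_size_um`, `field_size_um`, `origin_mm`.
#' @export
sim_bead_stack <- function(field_size_um = c(100, 100, 10),
                           voxel_size_um = c(0.5, 0.5, 1),
                           density = 20,
                           psf_sigma_um = 0.3,
                           amplitude = 100,
                           background = 10,
                           noise_sd = 2,
                           seed = 1L,
                           origin_mm = c(0, 0)) {
  if (length(field_size_um) != 3L || length(voxel_size_um) != 3L)
    stop_config("`field_size_um` and `voxel_size_um` must have length 3")
  if (any(voxel_size_um <= 0)) stop_config("`voxel_size_um` must be > 0")
  dims <- field_size_um / voxel_size_um
  if (any(abs(dims - round(dims)) > 1e-8))
    stop_config("`field_size_um` must be an integer multiple of `voxel_size_um`")
  dims <- as.integer(round(dims))
  if (any(dims < 1L)) stop_config("degenerate field: zero voxels along an axis")
  check_number(psf_sigma_um, "psf_sigma_um", positive = TRUE)
  if (noise_sd < 0) stop_config("`noise_sd` must be >= 0")

  area_1e4 <- field_size_um[1] * field_size_um[2] / 1e4
  set.seed(as.integer(seed))
  if (is.function(density)) {
    # thinning against the density ceiling over a probe grid
    gx <- seq(0, field_size_um[1], length.out = 64)
    gy <- seq(0, field_size_um[2], length.out = 64)
    dmax <- max(outer(gx, gy, density))
    if (dmax < 0) stop_config("density field must be >= 0")
    n0 <- rpois(1L, dmax * area_1e4)
    x <- runif(n0, 0, field_size_um[1])
    y <- runif(n0, 0, field_size_um[2])
    keep <- if (n0 > 0) runif(n0) * dmax <= density(x, y) else logical(0)
    x <- x[keep]; y <- y[keep]
  } else {
    check_number(density, "density")
    if (density < 0) stop_config("`density` must be >= 0")
    n0 <- rpois(1L, density * area_1e4)
    x <- runif(n0, 0, field_size_um[1])
    y <- runif(n0, 0, field_size_um[2])
  }
  z <- runif(length(x), 0, field_size_um[3])
  beads <- tibble(x_um = x, y_um = y, z_um = z)

  stack <- array(0, dim = dims)
  if (nrow(beads) > 0) {
    half <- ceiling(4 * psf_sigma_um / voxel_size_um)
    cx <- (seq_len(dims[1]) - 0.5) * voxel_size_um[1]
    cy <- (seq_len(dims[2]) - 0.5) * voxel_size_um[2]
    cz <- (seq_len(dims[3]) - 0.5) * voxel_size_um[3]
    for (b in seq_len(nrow(beads))) {
      i0 <- as.integer(floor(beads$x_um[b] / voxel_size_um[1])) + 1L
      j0 <- as.integer(floor(beads$y_um[b] / voxel_size_um[2])) + 1L
      k0 <- as.integer(floor(beads$z_um[b] / voxel_size_um[3])) + 1L
      ii <- max(1L, i0 - half[1]):min(dims[1], i0 + half[1])
      jj <- max(1L, j0 - half[2]):min(dims[2], j0 + half[2])
      kk <- max(1L, k0 - half[3]):min(dims[3], k0 + half[3])
      gx <- exp(-(cx[ii] - beads$x_um[b])^2 / (2 * psf_sigma_um^2))
      gy <- exp(-(cy[jj] - beads$y_um[b])^2 / (2 * psf_sigma_um^2))
      gz <- exp(-(cz[kk] - beads$z_um[b])^2 / (2 * psf_sigma_um^2))
      blob <- amplitude * outer(outer(gx, gy), gz)
      stack[ii, jj, kk] <- stack[ii, jj, kk] + blob
    }
  }
  stack <- stack + background
  if (noise_sd > 0) stack <- stack + array(rnorm(length(stack), 0, noise_sd), dims)
  stack[stack < 0] <- 0

  structure(list(intensities = stack, beads = beads,
                 voxel_size_um = voxel_size_um,
                 field_size_um = field_size_um,
                 origin_mm = origin_mm),
            class = "bead_stack")
}

#' Hertz contact force for a spherical indenter
#'
#' Forward model `F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)` with
#' `E` in kPa, `R` and `delta` in µm, yielding force in nN (1 kPa = 1 nN/µm²).
#' Negative indentations contribute zero force.
#'
#' @param delta_um Indentation depth(s), µm.
#' @param E_kpa Young's modulus, kPa.
#' @param tip_radius_um Indenter radius, µm.
#' @param poisson_ratio Poisson ratio of the sample (0, 0.5].
#' @return Force(s), nN.
#' @export
hertz_force <- function(delta_um, E_kpa, tip_radius_um, poisson_ratio = 0.5) {
  d <- pmax(delta_um, 0)
  (4 / 3) * (E_kpa / (1 - poisson_ratio^2)) * sqrt(tip_radius_um) * d^1.5
}

#' Simulate an AFM force-indentation curve
#'
#' Generates an approach curve from the spherical-indenter Hertz model: flat
#' (noise-only) baseline before the contact point, then the Hertz force rise.
#' The recorded position axis is the piezo position, which past contact
#' exceeds the tip-sample indentation by the cantilever deflection
#' (force / spring constant), as in a real instrument.
#'
#' @param E_kpa True Young's modulus, kPa (> 0).
#' @param tip_radius_um Tip radius, µm (default 5, a 10 µm diameter sphere).
#' @param poisson_ratio Sample Poisson ratio in (0, 0.5].
#' @param contact_um Contact point along the approach axis, µm.
#' @param max_indentation_um Maximum indentation depth, µm; must not exceed
#'   the tip radius (Hertz validity).
#' @param n_points Number of samples (>= 16).
#' @param noise_sd_nn Additive Gaussian force noise, nN.
#' @param spring_constant_n_m Cantilever spring constant, N/m (default 1).
#' @param seed Integer seed.
#'
#' @return A tibble of class `force_curve` with columns `position_um`,
#'   `force_nN` and attributes `tip_radius_um`, `spring_constant_n_m`,
#'   `poisson_ratio`, plus ground truth `E_true_kpa` and `contact_true_um`.
#' @export
sim_force_curve <- function(E_kpa,
                            tip_radius_um = 5,
                            poisson_ratio = 0.5,
                            contact_um = 2,
                            max_indentation_um = 1,
                            n_points = 200L,
                            noise_sd_nn = 0,
                            spring_constant_n_m = 1,
                            seed = 1L) {
  check_number(E_kpa, "E_kpa", positive = TRUE)
  check_number(tip_radius_um, "tip_radius_um", positive = TRUE)
  if (poisson_ratio <= 0 || poisson_ratio > 0.5)
    stop_config("`poisson_ratio` must be in (0, 0.5]")
  if (max_indentation_um > tip_radius_um)
    stop_config("`max_indentation_um` exceeds the tip radius: outside Hertz validity")
  if (n_points < 16L) stop_config("`n_points` must be >= 16")

  z_tip <- seq(0, contact_um + max_indentation_um, length.out = n_points)
  delta <- pmax(z_tip - contact_um, 0)
  f_true <- hertz_force(delta, E_kpa, tip_radius_um, poisson_ratio)
  k_nn_per_um <- spring_constant_n_m * 1000           # 1 N/m = 1000 nN/µm
  position <- z_tip + f_true / k_nn_per_um            # piezo = tip path + deflection
  set.seed(as.integer(seed))
  force <- f_true + if (noise_sd_nn > 0) rnorm(n_points, 0, noise_sd_nn) else 0

  new_force_curve(tibble(position_um = position, force_nN = force),
                  tip_radius_um = tip_radius_um,
                  spring_constant_n_m = spring_constant_n_m,
                  poisson_ratio = poisson_ratio,
                  E_true_kpa = E_kpa,
                  contact_true_um = contact_um)
}

new_force_curve <- function(df, tip_radius_um, spring_constant_n_m,
                            poisson_ratio, ...) {
  extra <- list(...)
  out <- as_tibble(df)
  attr(out, "tip_radius_um") <- tip_radius_um
  attr(out, "spring_constant_n_m") <- spring_constant_n_m
  attr(out, "poisson_ratio") <- poisson_ratio
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("force_curve", class(out))
  out
}

#' Simulate a paired bead-density / stiffness gradient dataset
#'
#' Draws calibration-style paired measurements from a generating calibration
#' model: densities at given values (or a regular grid of AFM-style
#' locations), true stiffness from the model, and optional Gaussian noise on
#' both axes. With zero noise the output satisfies the generating model
#' exactly, so fitting the same family recovers the generator parameters.
#'
#' @param model A [gel_calibration] object (see [calibration_model()]), used
#'   as ground truth.
#' @param densities Numeric vector of true bead densities (per 10^4 µm²);
#'   for a logit model they must lie strictly inside `(x_lo, x_hi)`.
#' @param density_noise_sd,stiffness_noise_sd Gaussian noise SDs added to
#'   the observed density and stiffness.
#' @param spacing_mm Spacing of the synthetic measurement locations, mm.
#' @param seed Integer seed.
#'
#' @return A tibble of class `calibration_points` with columns `x_mm`,
#'   `y_mm`, `density_mean`, `density_sem`, `stiffness_mean`,
#'   `stiffness_sem`, plus attributes `truth` (the generating model) and the
#'   noise levels.
#' @export
sim_gradient <- function(model,
                         densities,
                         density_noise_sd = 0,
                         stiffness_noise_sd = 0,
                         spacing_mm = 0.5,
                         seed = 1L) {
  if (!inherits(model, "gel_calibration"))
    stop_config("`model` must be a gel_calibration object")
  if (length(densities) < 1L) stop_config("`densities` must be non-empty")
  truth_y <- eval_calibration(model, densities)
  set.seed(as.integer(seed))
  n <- length(densities)
  obs_x <- densities + if (density_noise_sd > 0) rnorm(n, 0, density_noise_sd) else 0
  obs_y <- truth_y + if (stiffness_noise_sd > 0) rnorm(n, 0, stiffness_noise_sd) else 0
  out <- tibble(
    x_mm = spacing_mm * (seq_len(n) - 1L),
    y_mm = 0,
    density_mean = obs_x,
    density_sem = density_noise_sd / 2,
    stiffness_mean = obs_y,
    stiffness_sem = stiffness_noise_sd / 3
  )
  attr(out, "truth") <- model
  attr(out, "density_noise_sd") <- density_noise_sd
  attr(out, "stiffness_noise_sd") <- stiffness_noise_sd
  class(out) <- c("calibration_points", class(out))
  out
}

# Render filled rotated ellipses onto a matrix (adds `intensity` inside).
render_ellipses <- function(img, px_um, ellipses) {
  nr <- nrow(img); nc <- ncol(img)
  xs <- (seq_len(nr) - 0.5) * px_um
  ys <- (seq_len(nc) - 0.5) * px_um
  for (e in seq_len(nrow(ellipses))) {
    a <- ellipses$length_um[e] / 2
    b <- ellipses$width_um[e] / 2
    th <- ellipses$angle_deg[e] * pi / 180
    dx <- outer(xs - ellipses$x_um[e], rep(1, nc))
    dy <- outer(rep(1, nr), ys - ellipses$y_um[e])
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    img[inside] <- img[inside] + ellipses$intensity[e]
  }
  img
}

#' Simulate a two-channel adhesion image pair
#'
#' Renders elliptical adhesions into two channels at stated intensities, for
#' testing ratiometric analysis and colocalization. Each adhesion is
#' described by its center, length, width, orientation and per-channel
#' intensity (an intensity of 0 leaves the adhesion out of that channel).
#'
#' @param adhesions Tibble with columns `x_um`, `y_um`, `length_um`,
#'   `width_um`, `angle_deg`, `intensity_a`, `intensity_b`.
#' @param image_size_um Square field size, µm.
#' @param pixel_size_um Pixel size, µm.
#' @param noise_sd Additive Gaussian noise SD (both channels).
#' @param seed Integer seed.
#' @return List with `channel_a`, `channel_b` (matrices), `mask_a`, `mask_b`
#'   (logical ground-truth masks) and `pixel_size_um`.
#' @export
sim_adhesion_pair <- function(adhesions,
                              image_size_um = 40,
                              pixel_size_um = 0.08,
                              noise_sd = 0,
                              seed = 1L) {
  npx <- as.integer(round(image_size_um / pixel_size_um))
  blank <- matrix(0, npx, npx)
  ea <- adhesions[adhesions$intensity_a > 0, , drop = FALSE]
  eb <- adhesions[adhesions$intensity_b > 0, , drop = FALSE]
  mk <- function(sub, col) {
    if (nrow(sub) == 0) return(blank)
    sub$intensity <- sub[[col]]
    render_ellipses(blank, pixel_size_um, sub)
  }
  a <- mk(ea, "intensity_a"); b <- mk(eb, "intensity_b")
  set.seed(as.integer(seed))
  if (noise_sd > 0) {
    a <- pmax(a + matrix(rnorm(npx^2, 0, noise_sd), npx), 0)
    b <- pmax(b + matrix(rnorm(npx^2, 0, noise_sd), npx), 0)
  }
  list(channel_a = a, channel_b = b,
       mask_a = mk(ea, "intensity_a") > 0,
       mask_b = mk(eb, "intensity_b") > 0,
       pixel_size_um = pixel_size_um)
}

#' Simulate a nucleus/cytoplasm phantom cell
#'
#' Builds a two-channel phantom: a nucleus-marker channel (bright disc) and a
#' signal channel with stated mean intensities inside the nucleus and in the
#' surrounding cytoplasmic ring, for testing nuclear-to-cytoplasmic ratio and
#' shape quantification. The cell body is an ellipse containing the nucleus.
#'
#' @param image_size_um Square field size, µm.
#' @param pixel_size_um Pixel size, µm.
#' @param nucleus_radius_um Nucleus disc radius, µm.
#' @param cell_axes_um Cell ellipse semi-axes `c(a, b)`, µm.
#' @param nucleus_intensity,cytoplasm_intensity Signal-channel mean
#'   intensities inside the nucleus and in the cytoplasm.
#' @param background Signal background outside the cell.
#' @param noise_sd Additive Gaussian noise SD (signal channel).
#' @param seed Integer seed.
#' @return List with `nucleus_channel`, `signal_channel` (matrices),
#'   `nucleus_mask`, `cell_mask` (logical) and `pixel_size_um`.
#' @export
sim_cell_phantom <- function(image_size_um = 60,
                             pixel_size_um = 0.25,
                             nucleus_radius_um = 8,
                             cell_axes_um = c(20, 12),
                             nucleus_intensity = 200,
                             cytoplasm_intensity = 100,
                             background = 0,
                             noise_sd = 0,
                             seed = 1L) {
  npx <- as.integer(round(image_size_um / pixel_size_um))
  xs <- (seq_len(npx) - 0.5) * pixel_size_um - image_size_um / 2
  dx <- outer(xs, rep(1, npx)); dy <- outer(rep(1, npx), xs)
  nucleus <- dx^2 + dy^2 <= nucleus_radius_um^2
  cell <- (dx / cell_axes_um[1])^2 + (dy / cell_axes_um[2])^2 <= 1
  signal <- matrix(background, npx, npx)
  signal[cell] <- cytoplasm_intensity
  signal[nucleus] <- nucleus_intensity
  set.seed(as.integer(seed))
  if (noise_sd > 0)
    signal <- pmax(signal + matrix(rnorm(npx^2, 0, noise_sd), npx), 0)
  list(nucleus_channel = matrix(ifelse(nucleus, 255, 0), npx, npx),
       signal_channel = signal,
       nucleus_mask = nucleus,
       cell_mask = cell,
       pixel_size_um = pixel_size_um)
}
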