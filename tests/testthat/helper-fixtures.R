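# Shared fixtures: the published calibration constants, canonical study
# designs, and a brute-force oracle for the ratio rule.

linear_truth <- function() {
  calibration_model("linear", c(a = 0.0044, b = 0.903))
}

logit_truth <- function() {
  calibration_model("logit", c(y_half = 29.221, rate = 18.884,
                               x_lo = -179.59, x_hi = 4720))
}

# study designs for recovery simulations (20 points each)
linear_design <- function(n = 20) seq(0, 4000, length.out = n)
logit_design  <- function(n = 20) seq(500, 4200, length.out = n)

stiffness_range <- function(model, dens) {
  diff(range(predict(model, dens)$stiffness_kpa))
}

# Independent per-pixel oracle for the four-case ratio rule, written
# directly from the published case enumeration (scalar, no vectorised
# shortcuts shared with the implementation).
ratio_oracle_pixel <- function(a, b) {
  if (a == 0 && b == 0) return(0)
  if (a > 0 && b == 0) return(10)
  q <- a / b
  if (q <= 0.1) return(0.1)
  if (q >= 10) return(10)
  q
}

# Small noise-free bead phantom used by several tests.
small_phantom <- function(density = 20, seed = 7, noise_sd = 0,
                          background = 0) {
  sim_bead_stack(field_size_um = c(100, 100, 5),
                 voxel_size_um = c(0.5, 0.5, 1),
                 density = density, noise_sd = noise_sd,
                 background = background, seed = seed)
}

# A single elliptical adhesion bar rendered into channel A.
bar_image <- function(length_um = 3.5, width_um = 0.5, angle_deg = 0,
                      pixel_size_um = 0.08) {
  adh <- tibble::tibble(x_um = 10, y_um = 10, length_um = length_um,
                        width_um = width_um, angle_deg = angle_deg,
                        intensity_a = 100, intensity_b = 0)
  sim_adhesion_pair(adh, image_size_um = 20,
                    pixel_size_um = pixel_size_um)$channel_a
}
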