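# Per-cell and per-adhesion quantification: nuclear-to-cytoplasmic intensity
# ratio (1 µm perinuclear ring), cell area and roundness, adhesion lengths,
# the logarithmic length-vs-stiffness model, and stiffness lookup through a
# calibration model.

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Mean signal inside the nucleus mask divided by the mean signal in a
#' perinuclear cytoplasmic ring: the mask dilated by `ring_width_um` minus
#' the mask itself (the nucleus marker's own area is excluded). 3D input is
#' maximum-projected first. A nucleus whose ring would leave the image is
#' flagged, not dropped.
#'
#' @param signal Signal channel: 2D matrix or 3D array (max-projected).
#' @param nucleus_mask Logical (or 0/1) matrix, non-empty.
#' @param pixel_size_um Pixel size, µm.
#' @param ring_width_um Ring width, µm (default 1).
#' @return One-row tibble: `nc_ratio`, `nucleus_mean`, `ring_mean`,
#'   `nucleus_area_um2`, `flagged` (TRUE if the ring touches the border or is
#'   empty).
#' @export
nc_ratio <- function(signal, nucleus_mask, pixel_size_um, ring_width_um = 1) {
  if (is.array(signal) && length(dim(signal)) == 3L)
    signal <- apply(signal, c(1, 2), max)
  signal <- as_matrix_2d(signal, "signal")
  mask <- as_matrix_2d(nucleus_mask * 1, "nucleus_mask") > 0
  if (!any(mask)) stop_input("`nucleus_mask` is empty")
  if (!all(dim(signal) == dim(mask)))
    stop_input("signal and mask must have the same shape")
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE)

  r_px <- ring_width_um / pixel_size_um
  dil <- matrix(as.numeric(EBImage::dilate(EBImage::Image(mask * 1),
                                           disc_brush(r_px))),
                nrow(mask), ncol(mask)) > 0
  ring <- dil & !mask
  # flagged if the dilated nucleus reaches the border (ring clipped) or empty
  border <- any(dil[1, ]) || any(dil[nrow(dil), ]) ||
    any(dil[, 1]) || any(dil[, ncol(dil)])
  flagged <- border || !any(ring)
  nuc_mean <- mean(signal[mask])
  ring_mean <- if (any(ring)) mean(signal[ring]) else NA_real_
  tibble(nc_ratio = if (!is.na(ring_mean) && ring_mean > 0)
                      nuc_mean / ring_mean else NA_real_,
         nucleus_mean = nuc_mean, ring_mean = ring_mean,
         nucleus_area_um2 = sum(mask) * pixel_size_um^2,
         flagged = flagged)
}

#' Cell area and roundness from a cell mask
#'
#' Area is the pixel count times the pixel area. Roundness is the common
#' particle-analysis definition `4 * area / (pi * major_axis^2)`, with the
#' major axis length taken from the second central moments of the mask
#' (4 * sqrt of the largest eigenvalue, exact for ellipses): 1 for a disc,
#' b/a for an ellipse with semi-axes a > b.
#'
#' @param cell_mask Logical (or 0/1) matrix, non-empty.
#' @param pixel_size_um Pixel size, µm.
#' @return One-row tibble: `area_um2`, `roundness`, `major_axis_um`,
#'   `flagged` (mask touches the border or is degenerate, < 5 pixels).
#' @export
cell_shape <- function(cell_mask, pixel_size_um) {
  mask <- as_matrix_2d(cell_mask * 1, "cell_mask") > 0
  if (!any(mask)) stop_input("`cell_mask` is empty")
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  npx <- sum(mask)
  idx <- which(mask)
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  border <- any(rows == 1L) || any(rows == nrow(mask)) ||
    any(cols == 1L) || any(cols == ncol(mask))
  degenerate <- npx < 5L
  area <- npx * pixel_size_um^2
  if (degenerate) {
    return(tibble(area_um2 = area, roundness = NA_real_,
                  major_axis_um = NA_real_, flagged = TRUE))
  }
  cr <- rows - mean(rows); cc <- cols - mean(cols)
  covm <- matrix(c(mean(cr^2), mean(cr * cc), mean(cr * cc), mean(cc^2)), 2)
  ev <- eigen(covm, symmetric = TRUE)$values
  major_px <- 4 * sqrt(max(ev[1], 0))
  major_um <- major_px * pixel_size_um
  tibble(area_um2 = area,
         roundness = min(4 * area / (pi * major_um^2), 1),
         major_axis_um = major_um,
         flagged = border)
}

#' Segment adhesions and measure their lengths
#'
#' Thresholds the (preprocessed) adhesion channel, labels connected
#' components, drops components below a minimum area, and measures each
#' component's length as its geodesic diameter — the longest 8-connected
#' shortest path through the component (chamfer weights 1 and sqrt(2)) plus
#' one pixel to convert center-to-center into end-to-end distance. For thin
#' elongated adhesions this is their skeletal length; it is invariant to
#' rotation up to discretization.
#'
#' @param image 2D matrix (preprocessed adhesion channel) or a logical mask.
#' @param pixel_size_um Pixel size, µm.
#' @param threshold `"otsu"` or a fixed value; ignored for logical input.
#' @param min_area_px Minimum component size in pixels (default 4).
#' @return Tibble with one row per adhesion: `id`, `length_um`, `area_um2`,
#'   `row`, `col` (centroid, pixels). Empty (with a warning of class
#'   `gradgel_empty_mask`) when nothing survives the size filter.
#' @export
adhesion_lengths <- function(image, pixel_size_um, threshold = "otsu",
                             min_area_px = 4L) {
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (is.logical(image)) {
    mask <- image
  } else {
    image <- as_matrix_2d(image)
    if (all(image == image[1])) mask <- matrix(FALSE, nrow(image), ncol(image))
    else mask <- image > resolve_threshold(image, threshold)
  }
  empty <- tibble(id = integer(), length_um = numeric(), area_um2 = numeric(),
                  row = numeric(), col = numeric())
  if (!any(mask)) {
    warn("no adhesions above threshold", class = "gradgel_empty_mask")
    return(empty)
  }
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                nrow(mask), ncol(mask))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0L) {
    warn("no adhesions above the size filter", class = "gradgel_empty_mask")
    return(empty)
  }
  rows <- map(keep, function(comp) {
    idx <- which(lab == comp)
    rr <- ((idx - 1L) %% nrow(lab)) + 1L
    cc <- ((idx - 1L) %/% nrow(lab)) + 1L
    # crop to the bounding box before the geodesic pass
    sub <- lab[min(rr):max(rr), min(cc):max(cc), drop = FALSE] == comp
    diam_px <- geodesic_diameter_px(sub)
    tibble(id = comp,
           length_um = (diam_px + 1) * pixel_size_um,
           area_um2 = areas[comp] * pixel_size_um^2,
           row = mean(rr), col = mean(cc))
  })
  bind_rows(rows)
}

#' Fit the logarithmic adhesion-length vs stiffness model
#'
#' Least-squares fit of `length = alpha + beta * ln(E)` — rapid lengthening
#' at low stiffness followed by a plateau — with a linear-in-E alternative
#' fitted alongside for comparison by AICc. `beta > 0` indicates
#' mechanoresponsive lengthening.
#'
#' @param records Tibble with columns `length_um` and `stiffness_kpa`
#'   (all > 0); at least 5 records spanning at least a 3-fold stiffness
#'   range.
#' @return List of class `length_stiffness_fit`: `alpha`, `beta`, their
#'   `vcov`, `sigma`, `n`, `aicc_log`, `aicc_linear`, `preferred`
#'   (`"logarithmic"` or `"linear"`), and the underlying `lm` fits.
#' @export
fit_length_stiffness <- function(records) {
  need <- c("length_um", "stiffness_kpa")
  if (!all(need %in% names(records)))
    stop_input("`records` needs columns length_um and stiffness_kpa")
  E <- records$stiffness_kpa; L <- records$length_um
  keep <- is.finite(E) & is.finite(L)
  E <- E[keep]; L <- L[keep]
  if (any(E <= 0)) stop_input("stiffness values must be positive")
  if (length(E) < 5L) stop_fit("need at least 5 records")
  if (max(E) / min(E) < 3) stop_fit("records must span at least a 3-fold stiffness range")
  dat <- data.frame(L = L, E = E)
  f_log <- lm(L ~ log(E), data = dat)
  f_lin <- lm(L ~ E, data = dat)
  n <- length(E)
  a_log <- aicc_from_rss(sum(residuals(f_log)^2), n, 2L)
  a_lin <- aicc_from_rss(sum(residuals(f_lin)^2), n, 2L)
  co <- coef(f_log)
  V <- suppressWarnings(vcov(f_log))
  structure(list(alpha = unname(co[1]), beta = unname(co[2]),
                 vcov = V, sigma = suppressWarnings(summary(f_log))$sigma, n = n,
                 df_residual = f_log$df.residual,
                 aicc_log = a_log, aicc_linear = a_lin,
                 preferred = if (a_log <= a_lin) "logarithmic" else "linear",
                 fit_log = f_log, fit_linear = f_lin),
            class = "length_stiffness_fit")
}

#' @export
tidy.length_stiffness_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  tq <- qt(1 - (1 - conf.level) / 2, x$df_residual)
  tibble(term = c("alpha", "beta"),
         estimate = c(x$alpha, x$beta), std.error = unname(se),
         conf.low = c(x$alpha, x$beta) - tq * unname(se),
         conf.high = c(x$alpha, x$beta) + tq * unname(se))
}

#' @export
glance.length_stiffness_fit <- function(x, ...) {
  tibble(alpha = x$alpha, beta = x$beta, sigma = x$sigma, n = x$n,
         AICc_log = x$aicc_log, AICc_linear = x$aicc_linear,
         preferred = x$preferred)
}

#' @export
print.length_stiffness_fit <- function(x, ...) {
  cat(sprintf(
    "Adhesion length vs stiffness: length = %.3g + %.3g ln(E), n = %d (%s form preferred)\n",
    x$alpha, x$beta, x$n, x$preferred))
  invisible(x)
}

#' Attach calibrated local stiffness to positioned records
#'
#' Looks up the bead density at the nearest density-map tile for each record
#' position and converts it to stiffness with a calibration model, carrying
#' the model's confidence interval. Positions outside the map extent (beyond
#' half a tile from every tile center) are flagged and get no stiffness.
#'
#' @param records Tibble with columns `x_mm`, `y_mm` (one row per cell or
#'   adhesion).
#' @param density_map A `bead_density_map` (or tibble with `x_mm`, `y_mm`,
#'   `density`).
#' @param model A `gel_calibration`.
#' @param interval Band type for the CI (default `"confidence"`, the
#'   calibration curve's band).
#' @return `records` plus `density`, `stiffness_kpa`, `stiffness_ci_low`,
#'   `stiffness_ci_high`, `outside_map`.
#' @export
attach_stiffness <- function(records, density_map, model,
                             interval = "confidence") {
  if (!all(c("x_mm", "y_mm") %in% names(records)))
    stop_input("`records` needs columns x_mm and y_mm")
  if (!all(c("x_mm", "y_mm", "density") %in% names(density_map)))
    stop_input("`density_map` needs columns x_mm, y_mm, density")
  ts <- attr(density_map, "tile_size_um") %||% NULL
  half_mm <- if (!is.null(ts)) max(ts) / 2 / 1000 else {
    ux <- sort(unique(density_map$x_mm))
    if (length(ux) > 1) min(diff(ux)) else Inf
  }
  n <- nrow(records)
  dens <- rep(NA_real_, n); out_flag <- logical(n)
  for (i in seq_len(n)) {
    d2 <- (density_map$x_mm - records$x_mm[i])^2 +
      (density_map$y_mm - records$y_mm[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > half_mm * sqrt(2) + 1e-12) {
      out_flag[i] <- TRUE
    } else {
      dens[i] <- density_map$density[j]
    }
  }
  res <- records
  res$density <- dens
  res$stiffness_kpa <- NA_real_
  res$stiffness_ci_low <- NA_real_
  res$stiffness_ci_high <- NA_real_
  ok <- !out_flag
  if (any(ok)) {
    pr <- predict(model, dens[ok], interval = interval)
    res$stiffness_kpa[ok] <- pr$stiffness_kpa
    res$stiffness_ci_low[ok] <- pr$ci_low
    res$stiffness_ci_high[ok] <- pr$ci_high
  }
  res$outside_map <- out_flag
  res
}
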