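# Internal helpers: classed conditions, thresholding, local maxima,
# geodesic distances on binary masks.

stop_input <- function(msg, class = "gradgel_input_error") {
  abort(msg, class = c(class, "gradgel_error"))
}

stop_config <- function(msg) stop_input(msg, class = "gradgel_config_error")
stop_fit    <- function(msg) stop_input(msg, class = "gradgel_fit_error")
stop_domain <- function(msg) stop_input(msg, class = "gradgel_domain_error")
stop_parse  <- function(msg) stop_input(msg, class = "gradgel_parse_error")

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_config(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_config(sprintf("`%s` must be > 0", name))
  invisible(x)
}

# Otsu threshold on the raw intensity scale. EBImage::otsu() expects [0, 1];
# rescale, threshold, map back. A constant image gets its constant back
# (nothing can exceed it, so the mask is empty).
otsu_threshold <- function(img) {
  rng <- range(img)
  if (rng[1] == rng[2]) return(rng[1])
  scaled <- (img - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  rng[1] + thr * (rng[2] - rng[1])
}

resolve_threshold <- function(img, threshold, noise_floor = FALSE) {
  if (is.character(threshold)) {
    if (!identical(threshold, "otsu"))
      stop_config(sprintf("unknown threshold method '%s' (use 'otsu' or a number)",
                          threshold))
    thr <- otsu_threshold(img)
    if (noise_floor) {
      # Otsu misplaces its split on very unbalanced histograms (a few bright
      # blobs over a large noisy background); never threshold inside the
      # background noise. Median + 5 MAD scales with the image, so relative
      # (intensity-rescaling) invariance is preserved.
      thr <- max(thr, median(img) + 5 * stats::mad(img))
    }
    thr
  } else {
    check_number(threshold, "threshold")
  }
}

# Local maxima of a 2D image: pixels equal to the running maximum over a
# (2r+1)^2 window and above `floor`. Plateau maxima (exact ties) are collapsed
# to one marker per connected plateau.
local_maxima <- function(img, min_separation_px, floor) {
  r <- max(1L, as.integer(round(min_separation_px)))
  brush <- matrix(1, 2L * r + 1L, 2L * r + 1L)
  dil <- EBImage::dilate(EBImage::Image(img), brush)
  peaks <- (img >= as.numeric(dil)) & (img > floor)
  if (!any(peaks)) {
    return(tibble(row = integer(), col = integer(), intensity = numeric()))
  }
  lab <- EBImage::bwlabel(EBImage::Image(peaks * 1))
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  idx <- which(lab > 0L)
  rows <- ((idx - 1L) %% nrow(img)) + 1L
  cols <- ((idx - 1L) %/% nrow(img)) + 1L
  tibble(row = rows, col = cols, lab = lab[idx], intensity = img[idx]) |>
    group_by(.data$lab) |>
    summarise(row = as.integer(round(mean(.data$row))),
              col = as.integer(round(mean(.data$col))),
              intensity = max(.data$intensity), .groups = "drop") |>
    select("row", "col", "intensity")
}

# Single-source geodesic distances on a binary mask (8-connected, chamfer
# weights 1 / sqrt(2)), Dijkstra-like with a simple frontier loop. Masks are
# small (per-adhesion bounding boxes) so this is fast enough in plain R.
geodesic_distances <- function(mask, start_idx) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- matrix(Inf, nr, nc)
  dist[start_idx] <- 0
  active <- start_idx
  off_r <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  off_c <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  # optimal 3x3 chamfer weights (Borgefors): bound the deviation from
  # Euclidean length to about +/-4% at any orientation, vs +8% for 1/sqrt(2)
  w <- c(rep(0.9619, 4), rep(1.3604, 4))
  while (length(active) > 0L) {
    nxt <- integer(0)
    ar <- ((active - 1L) %% nr) + 1L
    ac <- ((active - 1L) %/% nr) + 1L
    for (k in seq_len(8L)) {
      rr <- ar + off_r[k]; cc <- ac + off_c[k]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      if (!any(ok)) next
      ni <- (cc[ok] - 1L) * nr + rr[ok]
      ok2 <- mask[ni] & (dist[active[ok]] + w[k] < dist[ni] - 1e-12)
      if (any(ok2)) {
        upd <- ni[ok2]
        dist[upd] <- dist[active[ok][ok2]] + w[k]
        nxt <- c(nxt, upd)
      }
    }
    active <- unique(nxt)
  }
  dist
}

# Geodesic diameter (longest shortest path, in pixel units) of a connected
# binary component, by the standard two-pass approximation: farthest point
# from an arbitrary start, then farthest point from there.
geodesic_diameter_px <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(NA_real_)
  if (length(idx) == 1L) return(0)
  d1 <- geodesic_distances(mask, idx[1L])
  p <- idx[which.max(d1[idx])]
  d2 <- geodesic_distances(mask, p)
  max(d2[idx][is.finite(d2[idx])])
}

# Disc structuring element with a given radius in pixels (odd-sized brush).
disc_brush <- function(radius_px) {
  size <- 2L * max(1L, as.integer(round(radius_px))) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

as_matrix_2d <- function(x, name = "image") {
  if (inherits(x, "Image")) x <- as.numeric(EBImage::imageData(x))
  if (!is.matrix(x) || !is.numeric(x))
    stop_input(sprintf("`%s` must be a numeric matrix", name))
  x
}
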