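# Ratiometric two-channel adhesion analysis: per-channel background
# subtraction and masking, the four-case per-pixel ratio rule with its
# {0} U [0.1, 10] output domain, log-scale rendering, and Pearson
# colocalization.

#' Rolling-ball-style background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the image with a disc structuring element (the classic rolling-ball idea)
#' and subtracts it, clamping at zero. Features smaller than the disc
#' survive; broad background is flattened.
#'
#' @param image 2D numeric matrix.
#' @param radius_px Disc radius, pixels (default 50).
#' @return Background-subtracted matrix (non-negative).
#' @export
subtract_background <- function(image, radius_px = 50) {
  image <- as_matrix_2d(image)
  check_number(radius_px, "radius_px", positive = TRUE)
  brush <- disc_brush(radius_px)
  bg <- EBImage::dilate(EBImage::erode(EBImage::Image(image), brush), brush)
  out <- image - matrix(as.numeric(bg), nrow(image), ncol(image))
  out[out < 0] <- 0
  out
}

#' Preprocess one channel for ratiometric analysis
#'
#' Background subtraction followed by threshold masking: pixels at or below
#' the threshold are set exactly to zero, pixels above it keep their
#' background-subtracted values. Each channel of a pair is processed
#' independently. If everything falls below threshold the result is all-zero
#' and a warning (class `gradgel_empty_mask`) is raised, not an error.
#'
#' @param image 2D numeric matrix (non-negative).
#' @param background_radius_px Rolling-ball disc radius; `NULL` or 0 skips
#'   background subtraction.
#' @param threshold `"otsu"` or a fixed value on the background-subtracted
#'   scale.
#' @return Masked matrix; every pixel is 0 or its retained intensity.
#' @export
preprocess_channel <- function(image, background_radius_px = 50,
                               threshold = "otsu") {
  image <- as_matrix_2d(image)
  if (any(image < 0)) stop_input("`image` must be non-negative")
  if (!is.null(background_radius_px) && background_radius_px > 0)
    image <- subtract_background(image, background_radius_px)
  thr <- resolve_threshold(image, threshold)
  out <- image
  out[out <= thr] <- 0
  if (all(out == 0))
    warn("all pixels fell below the threshold: empty mask",
         class = "gradgel_empty_mask")
  out
}

#' Two-channel ratiometric image (four-case pixel rule)
#'
#' Divides channel A by channel B pixel by pixel under the four-case rule
#' for masked (zero-containing) channels: (1) both pixels zero -> 0;
#' (2) ratio <= 0.1 -> 0.1; (3) ratio >= 10, or A > 0 with B = 0 -> 10;
#' (4) otherwise the plain ratio A/B. The output domain is therefore exactly
#' \{0\} U \[0.1, 10\]: zero marks "no signal in either channel", and two
#' orders of magnitude of relative enrichment are kept.
#'
#' @param channel_a,channel_b Preprocessed (masked) matrices of equal shape;
#'   A is the numerator.
#' @return Matrix of class `ratio_image` with a `provenance` attribute.
#' @export
ratio_image <- function(channel_a, channel_b) {
  a <- as_matrix_2d(channel_a, "channel_a")
  b <- as_matrix_2d(channel_b, "channel_b")
  if (!all(dim(a) == dim(b)))
    stop_input("channel images must have the same shape")
  if (any(a < 0) || any(b < 0)) stop_input("channels must be non-negative")
  r <- matrix(0, nrow(a), ncol(a))
  both_zero <- a == 0 & b == 0
  a_only <- a > 0 & b == 0
  rest <- !both_zero & !a_only
  q <- a[rest] / b[rest]
  q[q <= 0.1] <- 0.1
  q[q >= 10] <- 10
  r[rest] <- q
  r[a_only] <- 10
  # both_zero stays 0
  attr(r, "provenance") <- list(rule = "four-case", clamp = c(0.1, 10))
  class(r) <- c("ratio_image", class(r))
  r
}

# Jet-like colour lookup table (256 x 3, values in [0, 1]): the classic
# blue -> cyan -> yellow -> red ramp.
jet_lut <- function(n = 256L) {
  t <- seq(0, 1, length.out = n)
  ramp <- function(u) pmin(pmax(1.5 - abs(u), 0), 1)
  cbind(r = ramp(4 * t - 3), g = ramp(4 * t - 2), b = ramp(4 * t - 1))
}

#' Render a ratio image on a log scale
#'
#' Maps every positive pixel by `log10` from \[0.1, 10\] onto \[-1, 1\] and
#' then through a jet-like colour table (0.1 and 10 hit the table endpoints,
#' 1.0 the midpoint); zero pixels are rendered a fixed grey. Deterministic.
#'
#' @param r A `ratio_image` (or matrix with values in \{0\} U \[0.1, 10\]).
#' @param grey Grey level for zero pixels (default 0.5).
#' @return An `nrow x ncol x 3` RGB array in \[0, 1\].
#' @export
log_display <- function(r, grey = 0.5) {
  r <- unclass(r)
  lut <- jet_lut()
  out <- array(grey, dim = c(nrow(r), ncol(r), 3L))
  pos <- which(r > 0)
  if (length(pos) > 0) {
    t <- (log10(r[pos]) + 1) / 2            # [0.1, 10] -> [0, 1]
    t <- pmin(pmax(t, 0), 1)
    idx <- as.integer(round(t * 255)) + 1L
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[pos] <- lut[idx, ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Pearson colocalization coefficient of two channels
#'
#' Standard Pearson correlation of pixel intensities over a chosen pixel
#' population: all pixels of the overlap (the JACoP-style default) or only
#' the union of the two channel masks (nonzero in either channel).
#'
#' @param channel_a,channel_b Matrices of equal shape.
#' @param mask_policy `"all"` or `"union"`.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_coloc <- function(channel_a, channel_b,
                          mask_policy = c("all", "union")) {
  mask_policy <- match.arg(mask_policy)
  a <- as_matrix_2d(channel_a, "channel_a")
  b <- as_matrix_2d(channel_b, "channel_b")
  if (!all(dim(a) == dim(b)))
    stop_input("channel images must have the same shape")
  sel <- if (mask_policy == "union") (a != 0) | (b != 0) else
    matrix(TRUE, nrow(a), ncol(a))
  av <- a[sel]; bv <- b[sel]
  if (length(av) < 2L || var(av) == 0 || var(bv) == 0)
    stop_input("Pearson coefficient undefined: a channel has zero variance",
               class = "gradgel_undefined_error")
  cor(av, bv)
}
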