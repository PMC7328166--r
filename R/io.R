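# File I/O: multi-page TIFF stacks with a JSON metadata sidecar (voxel size,
# origin, intensity scale), and CSV matrices carrying a two-line physical
# coordinate header so spatial pairing never depends on array order.

#' Write / read an image stack as multi-page TIFF
#'
#' Slices along z become TIFF pages (32-bit float, intensities scaled to
#' \[0, 1\] by a stored scale factor). Physical metadata — voxel size, origin
#' and the intensity scale — is written to a JSON sidecar `<path>.meta.json`,
#' since standard baseline TIFF tags cannot carry a z-spacing. Reading
#' without the sidecar requires an explicit `pixel_size_um`; otherwise it is
#' an error.
#'
#' @param stack A `bead_stack` or a plain 3D array.
#' @param path TIFF file path.
#' @param voxel_size_um,origin_mm Metadata for plain-array input (taken from
#'   the object for a `bead_stack`).
#' @return `write_image_stack()` returns `path` invisibly;
#'   `read_image_stack()` returns a `bead_stack` (with an empty ground-truth
#'   bead table).
#' @export
write_image_stack <- function(stack, path, voxel_size_um = NULL,
                              origin_mm = c(0, 0)) {
  if (inherits(stack, "bead_stack")) {
    arr <- stack$intensities
    voxel_size_um <- stack$voxel_size_um
    origin_mm <- stack$origin_mm
  } else {
    arr <- stack
    if (is.null(voxel_size_um))
      stop_input("`voxel_size_um` is required for plain-array input")
  }
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop_input("`stack` must be a 3D array or bead_stack")
  scale <- max(arr, 1e-12)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(format = "gradgel-stack", format_version = 1L,
         voxel_size_um = voxel_size_um, origin_mm = origin_mm,
         intensity_scale = scale, n_pages = length(pages)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @param pixel_size_um Fallback `c(x, y, z)` voxel size when no sidecar
#'   exists (a scalar is used for x and y with z = 1).
#' @export
read_image_stack <- function(path, pixel_size_um = NULL) {
  meta_path <- paste0(path, ".meta.json")
  scale <- 1
  origin_mm <- c(0, 0)
  if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    voxel <- as.numeric(m$voxel_size_um)
    scale <- m$intensity_scale %||% 1
    origin_mm <- as.numeric(m$origin_mm %||% c(0, 0))
  } else if (!is.null(pixel_size_um)) {
    voxel <- if (length(pixel_size_um) == 3L) as.numeric(pixel_size_um)
             else c(pixel_size_um, pixel_size_um, 1)
  } else {
    stop_input(paste0(
      "TIFF has no pixel-size metadata (missing ", basename(meta_path),
      "): supply `pixel_size_um` / --pixel-size"))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * scale
  structure(list(intensities = arr,
                 beads = tibble(x_um = numeric(), y_um = numeric(),
                                z_um = numeric()),
                 voxel_size_um = voxel,
                 field_size_um = dim(arr) * voxel,
                 origin_mm = origin_mm),
            class = "bead_stack")
}

#' Write / read a 2D channel image as single-page TIFF
#'
#' Same conventions as [write_image_stack()] (float TIFF, JSON sidecar with
#' the pixel size and intensity scale).
#'
#' @param image 2D matrix.
#' @param path TIFF path.
#' @param pixel_size_um Pixel size, µm.
#' @return `write_channel_image()`: `path`, invisibly.
#'   `read_channel_image()`: matrix with attribute `pixel_size_um`.
#' @export
write_channel_image <- function(image, path, pixel_size_um) {
  image <- as_matrix_2d(image)
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  scale <- max(image, 1e-12)
  tiff::writeTIFF(image / scale, path, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(
    list(format = "gradgel-image", format_version = 1L,
         pixel_size_um = pixel_size_um, intensity_scale = scale),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channel_image
#' @export
read_channel_image <- function(path, pixel_size_um = NULL) {
  meta_path <- paste0(path, ".meta.json")
  scale <- 1
  if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pixel_size_um <- m$pixel_size_um
    scale <- m$intensity_scale %||% 1
  } else if (is.null(pixel_size_um)) {
    stop_input(paste0(
      "TIFF has no pixel-size metadata (missing ", basename(meta_path),
      "): supply `pixel_size_um` / --pixel-size"))
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  out <- img * scale
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

#' Write / read a spatial map as CSV with a coordinate header
#'
#' Long-format maps (one row per tile/location) are written as a matrix of
#' values preceded by two comment lines with the physical tile-center
#' coordinates in mm, so spatial pairing never depends on array order.
#' Values round-trip bit-exactly (17 significant digits).
#'
#' @param map Tibble with `x_mm`, `y_mm` and one value column (`density` or
#'   `stiffness_kpa`), on a rectangular grid.
#' @param path CSV path.
#' @param value Name of the value column; default guesses `density` then
#'   `stiffness_kpa`.
#' @return `write_map_csv()`: `path`, invisibly. `read_map_csv()`: a tibble
#'   with `x_mm`, `y_mm` and the value column (classed as a
#'   `bead_density_map` / `stiffness_map` when the value column says so).
#' @export
write_map_csv <- function(map, path, value = NULL) {
  value <- value %||% intersect(c("density", "stiffness_kpa"), names(map))[1]
  if (is.na(value) || is.null(map[[value]]))
    stop_input("`map` needs a density or stiffness_kpa column")
  xs <- sort(unique(map$x_mm)); ys <- sort(unique(map$y_mm))
  M <- matrix(NA_real_, length(xs), length(ys))
  ix <- match(map$x_mm, xs); iy <- match(map$y_mm, ys)
  M[cbind(ix, iy)] <- map[[value]]
  f17 <- function(v) format(v, digits = 17, trim = TRUE, scientific = FALSE)
  lines <- c(
    sprintf("# gradgel map v1: %s", value),
    sprintf("# x_mm: %s", paste(f17(xs), collapse = ",")),
    sprintf("# y_mm: %s", paste(f17(ys), collapse = ",")),
    apply(M, 1, function(r) paste(f17(r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  get_vec <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(ln) != 1L)
      stop_parse(sprintf("map CSV is missing its `%s` coordinate header", key))
    as.numeric(strsplit(sub(sprintf("^# %s:\\s*", key), "", ln), ",")[[1]])
  }
  what <- sub("^# gradgel map v1:\\s*", "",
              grep("^# gradgel map v1:", hdr, value = TRUE))
  if (length(what) != 1L) stop_parse("not a gradgel map CSV")
  xs <- get_vec("x_mm"); ys <- get_vec("y_mm")
  body <- lines[!grepl("^#", lines)]
  M <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
  if (!all(dim(M) == c(length(xs), length(ys))))
    stop_parse("map CSV body does not match its coordinate header")
  out <- tibble(x_mm = rep(xs, times = length(ys)),
                y_mm = rep(ys, each = length(xs)),
                value = as.numeric(M))
  names(out)[3] <- what
  out <- out[is.finite(out[[what]]), ]
  cls <- if (what == "density") "bead_density_map"
         else if (what == "stiffness_kpa") "stiffness_map" else NULL
  if (!is.null(cls)) class(out) <- c(cls, class(out))
  out
}
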