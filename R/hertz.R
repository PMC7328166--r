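# AFM Hertz analysis: force-curve I/O, contact-point estimation,
# spherical-indenter Hertz fitting (linear in E, closed form), and
# consolidation of per-location replicates into a stiffness map.

# Indentation from piezo position: tip-sample indentation equals piezo
# travel past contact minus cantilever deflection (deflection = F / k).
indentation_um <- function(position_um, force_nn, contact_um,
                           spring_constant_n_m, baseline_nn = 0) {
  k_nn_per_um <- spring_constant_n_m * 1000
  (position_um - contact_um) - (force_nn - baseline_nn) / k_nn_per_um
}

validate_force_curve <- function(curve) {
  if (!inherits(curve, "force_curve"))
    stop_input("`curve` must be a force_curve")
  if (!all(c("position_um", "force_nN") %in% names(curve)))
    stop_input("force curve needs `position_um` and `force_nN` columns")
  if (nrow(curve) < 16L)
    stop_input("force curve must have at least 16 samples")
  if (any(diff(curve$position_um) <= 0))
    stop_parse("`position_um` must be strictly increasing")
  for (a in c("tip_radius_um", "spring_constant_n_m", "poisson_ratio")) {
    if (is.null(attr(curve, a)))
      stop_parse(sprintf("force curve is missing metadata field `%s`", a))
  }
  invisible(curve)
}

#' Write / read an AFM force curve as tab-separated text
#'
#' The interchange dialect is plain TSV with `# key: value` metadata lines
#' (tip radius, spring constant, Poisson ratio, optional location in mm)
#' followed by a header line `position_um<TAB>force_nN` and the data rows.
#' Values round-trip at full double precision.
#'
#' @param curve A `force_curve` tibble.
#' @param path File path.
#' @return `write_force_curve()` returns `path` invisibly;
#'   `read_force_curve()` returns a validated `force_curve`.
#' @export
write_force_curve <- function(curve, path) {
  validate_force_curve(curve)
  meta <- c(
    "# gradgel force curve v1",
    sprintf("# tip_radius_um: %s", format(attr(curve, "tip_radius_um"), digits = 17)),
    sprintf("# spring_constant_n_m: %s",
            format(attr(curve, "spring_constant_n_m"), digits = 17)),
    sprintf("# poisson_ratio: %s", format(attr(curve, "poisson_ratio"), digits = 17))
  )
  loc <- attr(curve, "location_mm")
  if (!is.null(loc))
    meta <- c(meta, sprintf("# location_mm: %s,%s",
                            format(loc[1], digits = 17), format(loc[2], digits = 17)))
  body <- paste(format(curve$position_um, digits = 17, trim = TRUE),
                format(curve$force_nN, digits = 17, trim = TRUE), sep = "\t")
  writeLines(c(meta, "position_um\tforce_nN", body), path)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([a-z_]+):\\s*(.+)$", ml))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  for (field in c("tip_radius_um", "spring_constant_n_m", "poisson_ratio")) {
    if (is.null(kv[[field]]))
      stop_parse(sprintf("force curve file is missing metadata field `%s`", field))
  }
  data_lines <- lines[!grepl("^#", lines)]
  if (length(data_lines) < 2L) stop_parse("no data rows in force curve file")
  hdr <- strsplit(data_lines[1], "\t", fixed = TRUE)[[1]]
  ip <- match("position_um", hdr); if_ <- match("force_nN", hdr)
  if (is.na(ip) || is.na(if_))
    stop_parse("force curve file must have `position_um` and `force_nN` columns")
  cells <- strsplit(data_lines[-1], "\t", fixed = TRUE)
  pos <- as.numeric(vapply(cells, `[[`, "", ip))
  frc <- as.numeric(vapply(cells, `[[`, "", if_))
  if (anyNA(pos) || anyNA(frc)) stop_parse("non-numeric values in force curve file")
  curve <- new_force_curve(
    tibble(position_um = pos, force_nN = frc),
    tip_radius_um = as.numeric(kv$tip_radius_um),
    spring_constant_n_m = as.numeric(kv$spring_constant_n_m),
    poisson_ratio = as.numeric(kv$poisson_ratio))
  if (!is.null(kv$location_mm))
    attr(curve, "location_mm") <-
      as.numeric(strsplit(kv$location_mm, ",", fixed = TRUE)[[1]])
  validate_force_curve(curve)
  curve
}

# Closed-form least-squares E (kPa) for fixed contact point and baseline:
# F - baseline = c(E) * g(delta), g = (4/3) sqrt(R) delta^1.5 / (1 - nu^2).
hertz_ls <- function(delta, force, tip_radius_um, poisson_ratio) {
  g <- (4 / 3) * sqrt(tip_radius_um) * pmax(delta, 0)^1.5 / (1 - poisson_ratio^2)
  sg2 <- sum(g^2)
  if (sg2 == 0) return(list(E = NA_real_, rss = sum(force^2), g = g, sg2 = 0))
  E <- sum(force * g) / sg2
  list(E = E, rss = sum((force - E * g)^2), g = g, sg2 = sg2)
}

#' Estimate the contact point of a force curve
#'
#' Exhaustive candidate search: for each candidate sample index the curve is
#' modelled as a flat baseline before the candidate and a Hertz rise after
#' it (closed-form least squares in E), and the candidate minimising the
#' total residual sum of squares wins. Deterministic; no derivative
#' heuristics.
#'
#' @param curve A `force_curve`.
#' @param min_pre,min_post Minimum samples required before and after contact.
#' @return Contact position, µm, with attributes `baseline_nN` and `index`.
#' @export
estimate_contact_point <- function(curve, min_pre = 4L, min_post = 8L) {
  validate_force_curve(curve)
  pos <- curve$position_um; frc <- curve$force_nN
  n <- length(pos)
  R <- attr(curve, "tip_radius_um")
  nu <- attr(curve, "poisson_ratio")
  k <- attr(curve, "spring_constant_n_m")
  cand <- seq.int(min_pre, n - min_post)
  if (length(cand) == 0L) stop_fit("curve too short for contact search")

  best <- list(rss = Inf, i = NA_integer_, E = NA_real_, base = NA_real_,
               sg2 = 0)
  csum <- cumsum(frc); csum2 <- cumsum(frc^2)
  for (i in cand) {
    base <- csum[i] / i
    rss_pre <- csum2[i] - i * base^2
    post <- (i + 1L):n
    delta <- indentation_um(pos[post], frc[post], pos[i], k, base)
    fit <- hertz_ls(delta, frc[post] - base, R, nu)
    rss <- rss_pre + fit$rss
    if (is.finite(rss) && rss < best$rss) {
      best <- list(rss = rss, i = i, E = fit$E, base = base, sg2 = fit$sg2)
    }
  }
  if (is.na(best$i) || !is.finite(best$E) || best$E <= 0)
    stop_fit("no post-contact rise found: cannot estimate a contact point")
  # Require the Hertz term to carry signal: t-statistic of E against the
  # residual noise of the winning fit.
  dfree <- max(n - 2L, 1L)
  sigma2 <- best$rss / dfree
  se_E <- sqrt(sigma2 / best$sg2)
  if (best$E / se_E < 3)
    stop_fit("no post-contact rise found: curve is flat within noise")

  # Continuous refinement between neighbouring samples: the true contact
  # rarely sits on the sampling grid. Baseline is frozen at the winning
  # candidate's value; the contact slides within +/- one sample.
  i <- best$i
  lo <- pos[max(i - 1L, 1L)]
  hi <- pos[min(i + 1L, n)]
  rss_at <- function(cc) {
    post <- pos > cc
    delta <- indentation_um(pos[post], frc[post], cc, k, best$base)
    fit <- hertz_ls(delta, frc[post] - best$base, R, nu)
    if (!is.finite(fit$E) || fit$E <= 0) return(Inf)
    sum((frc[!post] - best$base)^2) + fit$rss
  }
  opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-10 * max(hi - lo, 1e-9))
  contact <- if (is.finite(opt$objective) && opt$objective <= best$rss)
    opt$minimum else pos[i]
  structure(contact, baseline_nN = best$base, index = i)
}

#' Fit the spherical-indenter Hertz model to a force curve
#'
#' Given a contact point, the indentation is computed from the piezo
#' position minus the cantilever deflection (force / spring constant), the
#' pre-contact baseline is subtracted, and Young's modulus is the
#' closed-form least-squares solution of
#' `F = (4/3) E / (1 - nu^2) sqrt(R) delta^(3/2)`
#' over the indentations inside `fit_range_um`.
#'
#' @param curve A `force_curve`.
#' @param contact_um Contact point, µm; `NULL` (default) estimates it with
#'   [estimate_contact_point()].
#' @param fit_range_um Indentation window `c(lo, hi)`, µm; default
#'   `c(0.1, min(2, 0.3 R))`, the small-indentation Hertz regime.
#' @param baseline `"auto"` (mean pre-contact force) or a number, nN.
#' @return A list of class `hertz_fit`: `E_kpa`, `se_kpa`, `contact_um`,
#'   `baseline_nN`, `n_points`, `rss`, `sigma`, `fit_range_um`.
#' @export
fit_hertz <- function(curve, contact_um = NULL, fit_range_um = NULL,
                      baseline = "auto") {
  validate_force_curve(curve)
  R <- attr(curve, "tip_radius_um")
  nu <- attr(curve, "poisson_ratio")
  k <- attr(curve, "spring_constant_n_m")
  if (is.null(contact_um)) contact_um <- estimate_contact_point(curve)
  if (is.null(fit_range_um)) fit_range_um <- c(0.1, min(2, 0.3 * R))

  pre <- curve$position_um <= contact_um
  base <- if (identical(baseline, "auto")) {
    if (any(pre)) mean(curve$force_nN[pre]) else 0
  } else {
    check_number(baseline, "baseline", finite = TRUE)
  }
  delta <- indentation_um(curve$position_um, curve$force_nN, as.numeric(contact_um),
                          k, base)
  sel <- delta >= fit_range_um[1] & delta <= fit_range_um[2]
  if (sum(sel) < 8L)
    stop_fit(sprintf("only %d samples inside the fit range: need at least 8",
                     sum(sel)))
  fit <- hertz_ls(delta[sel], curve$force_nN[sel] - base, R, nu)
  if (!is.finite(fit$E)) stop_fit("Hertz fit failed (degenerate indentations)")
  dfree <- max(sum(sel) - 1L, 1L)
  sigma <- sqrt(fit$rss / dfree)
  structure(list(E_kpa = fit$E, se_kpa = sigma / sqrt(fit$sg2),
                 contact_um = as.numeric(contact_um), baseline_nN = base,
                 n_points = sum(sel), rss = fit$rss, sigma = sigma,
                 fit_range_um = fit_range_um),
            class = "hertz_fit")
}

#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble(term = "E_kpa", estimate = x$E_kpa, std.error = x$se_kpa)
}

#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(E_kpa = x$E_kpa, se_kpa = x$se_kpa, contact_um = x$contact_um,
         n_points = x$n_points, sigma = x$sigma)
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz fit: E = %.4g kPa (se %.3g), contact %.3g um, n = %d\n",
              x$E_kpa, x$se_kpa, x$contact_um, x$n_points))
  invisible(x)
}

#' Consolidate per-location Hertz fits into a stiffness map
#'
#' Takes one row per force curve (location plus fitted modulus, e.g. the
#' nine indentations of a 3 x 3 grid at each AFM location) and returns one
#' row per location with the arithmetic mean modulus, replicate count and
#' standard error. Locations where every fit failed (`NA` moduli) are kept
#' and flagged missing, never fabricated.
#'
#' @param fits Tibble with columns `x_mm`, `y_mm`, `E_kpa` (may contain
#'   `NA` for failed fits).
#' @return A tibble of class `stiffness_map`: `x_mm`, `y_mm`,
#'   `stiffness_kpa`, `n_fits`, `sem_kpa`, `missing`.
#' @export
stiffness_map <- function(fits) {
  need <- c("x_mm", "y_mm", "E_kpa")
  if (!all(need %in% names(fits)))
    stop_input("`fits` needs columns x_mm, y_mm, E_kpa")
  if (nrow(fits) == 0L) stop_input("`fits` is empty")
  out <- fits |>
    group_by(.data$x_mm, .data$y_mm) |>
    summarise(
      stiffness_kpa = if (all(is.na(.data$E_kpa))) NA_real_
                      else mean(.data$E_kpa, na.rm = TRUE),
      n_fits = sum(!is.na(.data$E_kpa)),
      sem_kpa = if (sum(!is.na(.data$E_kpa)) > 1L)
                  sd(.data$E_kpa, na.rm = TRUE) / sqrt(sum(!is.na(.data$E_kpa)))
                else NA_real_,
      .groups = "drop") |>
    mutate(missing = is.na(.data$stiffness_kpa)) |>
    arrange(.data$x_mm, .data$y_mm)
  class(out) <- c("stiffness_map", class(out))
  out
}
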