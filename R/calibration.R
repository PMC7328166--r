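# Bead-density -> stiffness calibration: spatial pairing of density and
# stiffness maps, linear and logit model fits with parameter covariance,
# delta-method confidence/prediction bands, validation of new AFM points
# against the band, and small-sample AICc model selection.
#
# Model families (x = bead density per 10^4 µm², y = Young's modulus, kPa):
#   linear:  y = a x + b
#   logit:   y = y_half + rate * ln((x - x_lo) / (x_hi - x)),  x_lo < x < x_hi
# The logit is the inverse-sigmoid used for wide stiffness ranges: steep near
# both abscissa limits, near-linear around the midpoint, where it passes
# through y_half.

#' Construct a calibration model from known parameters
#'
#' Builds a `gel_calibration` object directly (no fitting), e.g. as ground
#' truth for simulation or from published constants.
#'
#' @param kind `"linear"` or `"logit"`.
#' @param params Named numeric: `a`, `b` for linear (slope kPa per density
#'   unit, intercept kPa); `y_half`, `rate` (kPa) and `x_lo`, `x_hi`
#'   (density abscissa limits, `x_lo < x_hi`) for logit.
#' @param sigma Residual SD, kPa (0 for an exact model).
#' @param vcov Parameter covariance matrix (defaults to all zero).
#' @param ci_level Confidence level for bands (default 0.95).
#' @param density_domain Density range the model is trusted on.
#' @return A `gel_calibration` object.
#' @export
calibration_model <- function(kind = c("linear", "logit"), params,
                              sigma = 0, vcov = NULL, ci_level = 0.95,
                              density_domain = NULL) {
  kind <- match.arg(kind)
  want <- if (kind == "linear") c("a", "b") else c("y_half", "rate", "x_lo", "x_hi")
  if (!all(want %in% names(params)))
    stop_config(sprintf("`params` must name %s", paste(want, collapse = ", ")))
  coef <- as.numeric(params[want]); names(coef) <- want
  if (kind == "logit" && coef["x_lo"] >= coef["x_hi"])
    stop_config("logit model requires x_lo < x_hi")
  p <- length(coef)
  if (is.null(vcov)) vcov <- matrix(0, p, p, dimnames = list(want, want))
  if (is.null(density_domain)) {
    density_domain <- if (kind == "logit") unname(coef[c("x_lo", "x_hi")])
                      else c(0, Inf)
  }
  new_gel_calibration(kind, coef, vcov, sigma = sigma, df_residual = Inf,
                      n = NA_integer_, rss = NA_real_, aicc = NA_real_,
                      ci_level = ci_level, density_domain = density_domain)
}

new_gel_calibration <- function(kind, coef, vcov, sigma, df_residual, n, rss,
                                aicc, ci_level, density_domain,
                                convergence = NULL) {
  structure(list(kind = kind, coef = coef, vcov = vcov, sigma = sigma,
                 df_residual = df_residual, n = n, rss = rss, aicc = aicc,
                 ci_level = ci_level, density_domain = density_domain,
                 convergence = convergence),
            class = "gel_calibration")
}

# Point evaluation (no uncertainty); logit errors outside (x_lo, x_hi).
eval_calibration <- function(model, x) {
  if (model$kind == "linear") {
    model$coef[["a"]] * x + model$coef[["b"]]
  } else {
    lo <- model$coef[["x_lo"]]; hi <- model$coef[["x_hi"]]
    if (any(x <= lo | x >= hi))
      stop_domain(sprintf(
        "density outside the logit abscissa limits (%.4g, %.4g): stiffness undefined there",
        lo, hi))
    model$coef[["y_half"]] + model$coef[["rate"]] * log((x - lo) / (hi - x))
  }
}

#' Invert a calibration model (density from stiffness)
#'
#' Exact inverse of the fitted curve, mainly for diagnostics and testing:
#' for the logit, `x = (x_lo + x_hi * exp(z)) / (1 + exp(z))` with
#' `z = (y - y_half)/rate`; for the linear model, `x = (y - b)/a`.
#'
#' @param model A `gel_calibration`.
#' @param stiffness_kpa Stiffness value(s), kPa.
#' @return Bead density value(s).
#' @export
invert_calibration <- function(model, stiffness_kpa) {
  if (model$kind == "linear") {
    if (model$coef[["a"]] == 0) stop_domain("linear model with zero slope has no inverse")
    (stiffness_kpa - model$coef[["b"]]) / model$coef[["a"]]
  } else {
    z <- (stiffness_kpa - model$coef[["y_half"]]) / model$coef[["rate"]]
    (model$coef[["x_lo"]] + model$coef[["x_hi"]] * exp(z)) / (1 + exp(z))
  }
}

# Accept either aggregated calibration points or plain density/stiffness
# columns; returns a two-column data frame (density, stiffness).
calibration_xy <- function(points) {
  x <- points[["density_mean"]] %||% points[["density"]]
  y <- points[["stiffness_mean"]] %||% points[["stiffness_kpa"]] %||%
    points[["stiffness"]]
  if (is.null(x) || is.null(y))
    stop_input("`points` needs density(_mean) and stiffness(_mean|_kpa) columns")
  keep <- is.finite(x) & is.finite(y)
  data.frame(density = x[keep], stiffness = y[keep])
}

aicc_from_rss <- function(rss, n, p) {
  k <- p + 1  # + residual variance
  if (n - k - 1 <= 0) return(NA_real_)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Pair a bead-density map with an AFM stiffness map
#'
#' Matches each AFM location to the spatially nearest density measurement.
#' Density sub-tiles are first aggregated per parent stack (mean and SEM over
#' the 2 x 2 sub-tiles, n = 4 in the default workflow) when a `stack_id`
#' column is present; otherwise each density row is one candidate. AFM
#' locations with no density point within `tolerance_mm` are reported (with a
#' warning and in the `unmatched` attribute), never silently dropped.
#'
#' @param density_map A `bead_density_map` (or tibble with `x_mm`, `y_mm`,
#'   `density`).
#' @param stiff_map A `stiffness_map` (or tibble with `x_mm`, `y_mm`,
#'   `stiffness_kpa`, optionally `sem_kpa`).
#' @param tolerance_mm Maximum matching distance, mm (default 0.3, just over
#'   half the usual 0.5 mm AFM spacing).
#' @return A tibble of class `calibration_points`: `x_mm`, `y_mm`,
#'   `density_mean`, `density_sem`, `stiffness_mean`, `stiffness_sem`,
#'   `offset_mm`; attribute `unmatched` holds the unpaired AFM locations.
#' @export
pair_measurements <- function(density_map, stiff_map, tolerance_mm = 0.3) {
  if (!all(c("x_mm", "y_mm", "density") %in% names(density_map)))
    stop_input("`density_map` needs columns x_mm, y_mm, density")
  if (!all(c("x_mm", "y_mm") %in% names(stiff_map)))
    stop_input("`stiff_map` needs columns x_mm, y_mm")
  sy <- stiff_map[["stiffness_kpa"]] %||% stiff_map[["stiffness"]]
  if (is.null(sy)) stop_input("`stiff_map` needs a stiffness_kpa column")

  if ("stack_id" %in% names(density_map)) {
    dens <- density_map |>
      group_by(.data$stack_id) |>
      summarise(x_mm = mean(.data$x_mm), y_mm = mean(.data$y_mm),
                density_mean = mean(.data$density),
                density_sem = if (n() > 1L) sd(.data$density) / sqrt(n()) else 0,
                .groups = "drop")
  } else {
    dens <- tibble(x_mm = density_map$x_mm, y_mm = density_map$y_mm,
                   density_mean = density_map$density, density_sem = 0)
  }

  rows <- vector("list", nrow(stiff_map))
  for (i in seq_len(nrow(stiff_map))) {
    d2 <- (dens$x_mm - stiff_map$x_mm[i])^2 + (dens$y_mm - stiff_map$y_mm[i])^2
    j <- which.min(d2)
    rows[[i]] <- tibble(
      x_mm = stiff_map$x_mm[i], y_mm = stiff_map$y_mm[i],
      density_mean = dens$density_mean[j], density_sem = dens$density_sem[j],
      stiffness_mean = sy[i],
      stiffness_sem = (stiff_map[["sem_kpa"]] %||% rep(NA_real_, nrow(stiff_map)))[i],
      offset_mm = sqrt(d2[j]))
  }
  paired <- bind_rows(rows)
  ok <- paired$offset_mm <= tolerance_mm
  if (!any(ok))
    stop_input("no AFM location matched a density tile within the tolerance",
               class = "gradgel_pairing_error")
  unmatched <- paired[!ok, , drop = FALSE]
  if (nrow(unmatched) > 0L)
    warn(sprintf("%d AFM location(s) had no density match within %.3g mm",
                 nrow(unmatched), tolerance_mm))
  out <- paired[ok, , drop = FALSE]
  attr(out, "unmatched") <- unmatched
  class(out) <- c("calibration_points", class(out))
  out
}

#' Fit the linear bead-density calibration
#'
#' Ordinary least squares of stiffness on density, `y = a x + b`, with
#' parameter covariance — the model family used for narrow stiffness ranges.
#'
#' @param points `calibration_points` or a tibble with density and stiffness
#'   columns (at least 3 points).
#' @param ci_level Confidence level stored for bands (default 0.95).
#' @param weights Optional inverse-variance weights (e.g.
#'   `1 / stiffness_sem^2`); default unweighted.
#' @return A `gel_calibration` of kind `"linear"`.
#' @export
fit_linear_calibration <- function(points, ci_level = 0.95, weights = NULL) {
  xy <- calibration_xy(points)
  if (nrow(xy) < 3L) stop_fit("need at least 3 points for the linear fit")
  if (length(unique(xy$density)) < 2L)
    stop_fit("degenerate fit: all densities identical")
  fit <- if (is.null(weights)) lm(stiffness ~ density, data = xy)
         else lm(stiffness ~ density, data = xy, weights = weights)
  co <- coef(fit)
  coefs <- c(a = unname(co["density"]), b = unname(co["(Intercept)"]))
  V <- suppressWarnings(vcov(fit))[c("density", "(Intercept)"), c("density", "(Intercept)")]
  dimnames(V) <- list(c("a", "b"), c("a", "b"))
  rss <- sum(residuals(fit)^2)
  n <- nrow(xy)
  new_gel_calibration("linear", coefs, V, sigma = suppressWarnings(summary(fit))$sigma,
                      df_residual = fit$df.residual, n = n, rss = rss,
                      aicc = aicc_from_rss(rss, n, 2L), ci_level = ci_level,
                      density_domain = range(xy$density))
}

#' Fit the logit bead-density calibration
#'
#' Nonlinear least squares of
#' `y = y_half + rate * ln((x - x_lo)/(x_hi - x))` — the inverse-sigmoid
#' family used for wide stiffness ranges, steep where small density changes
#' meet large stiffness changes at both ends of the gradient. The abscissa
#' limits are kept strictly outside the data by an internal log-margin
#' reparameterisation (`x_lo = min(x) - exp(l_lo)`,
#' `x_hi = max(x) + exp(l_hi)`), so iterations can never step onto an
#' undefined logarithm; no values are silently clipped. The covariance of
#' the natural parameters is recovered from the transformed fit by the delta
#' method.
#'
#' @param points At least 5 calibration points.
#' @param init Optional named list with starting values for `x_lo` and
#'   `x_hi` (natural scale); defaults put the limits 10% of the density
#'   range outside the data.
#' @param ci_level Confidence level stored for bands.
#' @return A `gel_calibration` of kind `"logit"` with a `convergence` field.
#' @export
fit_logit_calibration <- function(points, init = NULL, ci_level = 0.95) {
  xy <- calibration_xy(points)
  n <- nrow(xy)
  if (n < 5L) stop_fit("need at least 5 points for the logit fit")
  x <- xy$density; y <- xy$stiffness
  xmin <- min(x); xmax <- max(x); xr <- xmax - xmin
  if (xr <= 0) stop_fit("degenerate fit: all densities identical")

  margin_lo <- if (!is.null(init$x_lo)) xmin - init$x_lo else 0.1 * xr
  margin_hi <- if (!is.null(init$x_hi)) init$x_hi - xmax else 0.1 * xr
  if (margin_lo <= 0 || margin_hi <= 0)
    stop_config("`init` limits must lie strictly outside the data range")
  L0 <- log((x - (xmin - margin_lo)) / ((xmax + margin_hi) - x))
  lin0 <- lm(y ~ L0)
  rate0 <- max(unname(coef(lin0)[2]), 1e-6)
  start <- list(y_half = unname(coef(lin0)[1]), l_rate = log(rate0),
                l_lo = log(margin_lo), l_hi = log(margin_hi))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y_half + exp(l_rate) * log((x - (xmin - exp(l_lo))) /
                                     ((xmax + exp(l_hi)) - x)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop_fit(sprintf("logit fit did not converge: %s",
                                         conditionMessage(e))))
  co <- coef(fit)
  coefs <- c(y_half = unname(co["y_half"]), rate = exp(unname(co["l_rate"])),
             x_lo = xmin - exp(unname(co["l_lo"])),
             x_hi = xmax + exp(unname(co["l_hi"])))
  # natural-scale covariance by the delta method:
  # d(rate)/d(l_rate) = rate, d(x_lo)/d(l_lo) = -exp(l_lo),
  # d(x_hi)/d(l_hi) = +exp(l_hi)
  tn <- c("y_half", "l_rate", "l_lo", "l_hi")
  J <- diag(c(1, coefs[["rate"]], -exp(unname(co["l_lo"])),
              exp(unname(co["l_hi"]))))
  Vt <- suppressWarnings(vcov(fit))[tn, tn]
  V <- J %*% Vt %*% t(J)
  nm <- c("y_half", "rate", "x_lo", "x_hi")
  dimnames(V) <- list(nm, nm)
  rss <- sum(residuals(fit)^2)
  conv <- list(converged = fit$convInfo$isConv %||% TRUE,
               iterations = fit$convInfo$finIter %||% NA_integer_,
               message = fit$convInfo$stopMessage %||% "")
  out <- new_gel_calibration("logit", coefs, V,
                             sigma = suppressWarnings(summary(fit))$sigma,
                             df_residual = n - 4L, n = n, rss = rss,
                             aicc = aicc_from_rss(rss, n, 4L),
                             ci_level = ci_level, density_domain = range(x),
                             convergence = conv)
  # the fitter's own (transformed) scale, kept for well-calibrated Wald CIs
  out$transformed <- list(coef = setNames(unname(co[tn]), tn), vcov = Vt,
                          xmin = xmin, xmax = xmax)
  out
}

# Gradient of the prediction wrt the natural parameters, for delta-method
# bands. Rows = points, cols = parameters.
calibration_gradient <- function(model, x) {
  if (model$kind == "linear") {
    cbind(a = x, b = rep(1, length(x)))
  } else {
    lo <- model$coef[["x_lo"]]; hi <- model$coef[["x_hi"]]
    rate <- model$coef[["rate"]]
    cbind(y_half = rep(1, length(x)),
          rate = log((x - lo) / (hi - x)),
          x_lo = -rate / (x - lo),
          x_hi = -rate / (hi - x))
  }
}

#' Predict stiffness (with a confidence band) from bead density
#'
#' Point prediction from the fitted calibration curve plus a two-sided band
#' at the model's `ci_level`: first-order (delta-method) propagation of the
#' parameter covariance, optionally widened by the residual variance for a
#' prediction interval. Densities outside the training domain are flagged as
#' extrapolation; for a logit model, densities outside `(x_lo, x_hi)` are a
#' domain error (stiffness is undefined there).
#'
#' @param object A `gel_calibration`.
#' @param density Bead densities (per 10^4 µm²).
#' @param interval `"confidence"` (band of the mean curve, the calibration
#'   plot's dashed lines) or `"prediction"` (band for a new measurement).
#' @param level Confidence level; defaults to the model's `ci_level`.
#' @param ... Unused.
#' @return Tibble: `density`, `stiffness_kpa`, `ci_low`, `ci_high`,
#'   `extrapolated`.
#' @export
predict.gel_calibration <- function(object, density,
                                    interval = c("confidence", "prediction"),
                                    level = NULL, ...) {
  interval <- match.arg(interval)
  level <- level %||% object$ci_level
  if (!is.numeric(density)) stop_input("`density` must be numeric")
  y <- eval_calibration(object, density)   # errors outside logit domain
  G <- calibration_gradient(object, density)
  var_mean <- rowSums((G %*% object$vcov) * G)
  v <- pmax(var_mean, 0) + if (interval == "prediction") object$sigma^2 else 0
  tq <- if (is.finite(object$df_residual) && object$df_residual > 0)
    qt(1 - (1 - level) / 2, object$df_residual) else qnorm(1 - (1 - level) / 2)
  half <- tq * sqrt(v)
  dom <- object$density_domain
  tibble(density = density, stiffness_kpa = as.numeric(y),
         ci_low = as.numeric(y - half), ci_high = as.numeric(y + half),
         extrapolated = density < dom[1] | density > dom[2])
}

#' Validate AFM measurements against the calibration band
#'
#' Flags each (density, measured stiffness) point as inside or outside the
#' calibration's two-sided band (a prediction interval by default, since a
#' new AFM measurement carries its own noise) and reports the overall
#' fraction inside.
#'
#' @param model A `gel_calibration`.
#' @param points Tibble with density and measured stiffness columns
#'   (`density`/`density_mean`, `stiffness_kpa`/`stiffness_mean`).
#' @param interval Band type, as in [predict.gel_calibration()].
#' @return Tibble of class `calibration_validation`: the points plus
#'   `predicted_kpa`, `ci_low`, `ci_high`, `inside`; attribute
#'   `fraction_within` (also via `glance()`).
#' @export
validate_calibration <- function(model, points, interval = "prediction") {
  xy <- calibration_xy(points)
  if (nrow(xy) == 0L) stop_input("no validation points supplied")
  pr <- predict(model, xy$density, interval = interval)
  out <- tibble(density = xy$density, stiffness_kpa = xy$stiffness,
                predicted_kpa = pr$stiffness_kpa,
                ci_low = pr$ci_low, ci_high = pr$ci_high,
                inside = xy$stiffness >= pr$ci_low & xy$stiffness <= pr$ci_high)
  attr(out, "fraction_within") <- mean(out$inside)
  class(out) <- c("calibration_validation", class(out))
  out
}

#' @export
glance.calibration_validation <- function(x, ...) {
  tibble(n = nrow(x), n_inside = sum(x$inside),
         fraction_within = attr(x, "fraction_within"))
}

#' Select the better-fitting calibration family
#'
#' Fits both the linear and the logit family and picks the one with the
#' lower small-sample-corrected information criterion (AICc). A margin below
#' `warn_margin` sets a near-tie flag.
#'
#' @param points At least 5 calibration points.
#' @param warn_margin AICc difference below which the choice is flagged as a
#'   near-tie (default 2).
#' @return List of class `calibration_selection`: `kind`, `margin` (AICc of
#'   the rejected minus the chosen family), `near_tie`, `linear`, `logit`,
#'   `model` (the winning fit).
#' @export
select_calibration <- function(points, warn_margin = 2) {
  lin <- fit_linear_calibration(points)
  lgt <- tryCatch(fit_logit_calibration(points), error = function(e) NULL)
  if (is.null(lgt)) {
    out <- list(kind = "linear", margin = Inf, near_tie = FALSE,
                linear = lin, logit = NULL, model = lin)
  } else {
    margin <- abs(lin$aicc - lgt$aicc)
    kind <- if (lgt$aicc < lin$aicc) "logit" else "linear"
    out <- list(kind = kind, margin = margin, near_tie = margin < warn_margin,
                linear = lin, logit = lgt,
                model = if (kind == "logit") lgt else lin)
  }
  if (out$near_tie)
    warn(sprintf("model families nearly tied (AICc margin %.2f)", out$margin))
  structure(out, class = "calibration_selection")
}

#' @export
print.calibration_selection <- function(x, ...) {
  cat(sprintf("Selected calibration family: %s (AICc margin %.3g%s)\n",
              x$kind, x$margin, if (x$near_tie) ", near tie" else ""))
  invisible(x)
}

#' @export
print.gel_calibration <- function(x, ...) {
  cat(sprintf("Bead-density calibration (%s)\n", x$kind))
  for (nm in names(x$coef))
    cat(sprintf("  %-7s %.6g\n", nm, x$coef[[nm]]))
  cat(sprintf("  sigma %.4g kPa; n = %s; density domain [%.4g, %.4g]\n",
              x$sigma, ifelse(is.na(x$n), "?", x$n),
              x$density_domain[1], x$density_domain[2]))
  invisible(x)
}

#' @export
tidy.gel_calibration <- function(x, conf.int = TRUE, conf.level = NULL, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  out <- tibble(term = names(x$coef), estimate = unname(x$coef),
                std.error = unname(se))
  if (conf.int) {
    level <- conf.level %||% x$ci_level
    tq <- if (is.finite(x$df_residual) && x$df_residual > 0)
      qt(1 - (1 - level) / 2, x$df_residual) else qnorm(1 - (1 - level) / 2)
    if (x$kind == "logit" && !is.null(x$transformed)) {
      # Wald intervals on the fitter's transformed scale (log rate,
      # log limit margins), mapped monotonically back: the raw-scale
      # sampling distributions are too skewed for symmetric intervals.
      ct <- x$transformed$coef
      set <- sqrt(pmax(diag(x$transformed$vcov), 0))
      lohi <- function(nm) ct[[nm]] + c(-1, 1) * tq * set[[nm]]
      ci <- rbind(
        y_half = lohi("y_half"),
        rate = exp(lohi("l_rate")),
        x_lo = sort(x$transformed$xmin - exp(lohi("l_lo"))),
        x_hi = sort(x$transformed$xmax + exp(lohi("l_hi"))))
      out$conf.low <- ci[, 1]
      out$conf.high <- ci[, 2]
    } else {
      out$conf.low <- out$estimate - tq * unname(se)
      out$conf.high <- out$estimate + tq * unname(se)
    }
  }
  out
}

#' @export
glance.gel_calibration <- function(x, ...) {
  tibble(kind = x$kind, sigma = x$sigma, rss = x$rss, AICc = x$aicc,
         n = x$n, df.residual = x$df_residual, ci_level = x$ci_level)
}

#' Write / read a calibration model file
#'
#' Serialises a `gel_calibration` as structured JSON (format version, kind,
#' parameters, covariance, residual sigma, degrees of freedom, CI level,
#' density domain). Reading validates the kind and required fields.
#'
#' @param model A `gel_calibration`.
#' @param path File path (`.json`).
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the `gel_calibration`.
#' @export
write_calibration <- function(model, path) {
  if (!inherits(model, "gel_calibration"))
    stop_input("`model` must be a gel_calibration")
  payload <- list(
    format = "gradgel-calibration", format_version = 1L,
    kind = model$kind,
    params = as.list(model$coef),
    vcov = unname(apply(model$vcov, 1, as.list)),
    sigma = model$sigma, df_residual = model$df_residual,
    n = model$n, rss = model$rss, aicc = model$aicc,
    ci_level = model$ci_level, density_domain = model$density_domain)
  if (!is.null(model$transformed))
    payload$transformed <- list(
      coef = as.list(model$transformed$coef),
      vcov = unname(apply(model$transformed$vcov, 1, as.list)),
      xmin = model$transformed$xmin, xmax = model$transformed$xmax)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "gradgel-calibration"))
    stop_parse("not a gradgel calibration file")
  if (!j$kind %in% c("linear", "logit"))
    stop_parse(sprintf("unknown calibration kind '%s'", j$kind))
  coef <- unlist(j$params)
  V <- matrix(unlist(j$vcov), length(coef), length(coef), byrow = TRUE,
              dimnames = list(names(coef), names(coef)))
  out <- new_gel_calibration(j$kind, coef, V, sigma = j$sigma,
                             df_residual = j$df_residual,
                             n = j$n %||% NA_integer_,
                             rss = j$rss %||% NA_real_,
                             aicc = j$aicc %||% NA_real_,
                             ci_level = j$ci_level,
                             density_domain = as.numeric(j$density_domain))
  if (!is.null(j$transformed)) {
    tc <- unlist(j$transformed$coef)
    out$transformed <- list(
      coef = tc,
      vcov = matrix(unlist(j$transformed$vcov), length(tc), length(tc),
                    byrow = TRUE, dimnames = list(names(tc), names(tc))),
      xmin = j$transformed$xmin, xmax = j$transformed$xmax)
  }
  out
}
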