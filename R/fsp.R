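#' Full scattering profile (FSP) curve
#'
#' One reflected-intensity profile over an exit coordinate around the
#' illumination point: azimuth in degrees (beam center at 180) or axial
#' distance in cm.
#'
#' @param abscissa strictly increasing positions (degrees or cm).
#' @param intensity nonnegative intensities, same length as `abscissa`.
#' @param direction `"azimuthal"` or `"longitudinal"`.
#' @param mu_s_reduced_label reduced scattering coefficient of the medium the
#'   curve belongs to, 1/cm (used to label curve families).
#' @param normalization one of `"raw"`, `"unit_area"`, `"reference_point"`.
#' @return An object of class `fsp_curve`.
#' @export
fsp_curve <- function(abscissa, intensity,
                      direction = c("azimuthal", "longitudinal"),
                      mu_s_reduced_label = NA_real_,
                      normalization = c("raw", "unit_area", "reference_point")) {
  direction <- match.arg(direction)
  normalization <- match.arg(normalization)
  abscissa <- as.numeric(abscissa)
  intensity <- as.numeric(intensity)
  if (length(abscissa) != length(intensity))
    stop("abscissa and intensity must have the same length")
  if (length(abscissa) < 2) stop("curve needs at least two points")
  if (any(diff(abscissa) <= 0)) stop("abscissa must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensity must be finite and nonnegative")
  structure(
    list(abscissa = abscissa, intensity = intensity, direction = direction,
         mu_s_reduced_label = mu_s_reduced_label,
         normalization = normalization),
    class = "fsp_curve")
}

#' @export
print.fsp_curve <- function(x, ...) {
  cat(sprintf(
    "FSP curve (%s, %d points on [%.4g, %.4g], mu_s' = %s /cm, %s)\n",
    x$direction, length(x$abscissa), min(x$abscissa), max(x$abscissa),
    format(x$mu_s_reduced_label), x$normalization))
  invisible(x)
}

#' @export
plot.fsp_curve <- function(x, ...) {
  xlab <- if (x$direction == "azimuthal") "azimuth (deg)" else "axial distance (cm)"
  graphics::plot(x$abscissa, x$intensity, type = "l", xlab = xlab,
                 ylab = "intensity", ...)
  invisible(x)
}

# trapezoid integral (internal)
.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Normalize an FSP curve
#'
#' `unit_area` scales so that the trapezoid integral equals one;
#' `reference_point` scales so that the intensity interpolated at `x0`
#' equals one. The integral may be restricted to a sub-`window` of the
#' curve's domain: curve families are compared on the analysis window where
#' the forward models are valid, so the normalization constant is taken
#' there as well.
#'
#' @param curve an [fsp_curve()].
#' @param method `"unit_area"` or `"reference_point"`.
#' @param window optional `c(lo, hi)` restricting the unit-area integral.
#' @param x0 reference position for `reference_point`.
#' @return The rescaled `fsp_curve`.
#' @export
normalize_curve <- function(curve, method = c("unit_area", "reference_point"),
                            window = NULL, x0 = NULL) {
  stopifnot(inherits(curve, "fsp_curve"))
  method <- match.arg(method)
  x <- curve$abscissa; y <- curve$intensity
  if (all(y == 0)) stop("cannot normalize an all-zero curve")
  if (method == "unit_area") {
    if (is.null(window)) {
      const <- .trapz(x, y)
    } else {
      idx <- x >= window[1] & x <= window[2]
      if (sum(idx) < 2) stop("window contains fewer than two grid points")
      const <- .trapz(x[idx], y[idx])
    }
  } else {
    if (is.null(x0)) stop("reference_point normalization needs x0")
    const <- stats::approx(x, y, xout = x0, rule = 2)$y
  }
  if (const <= 0) stop("normalization constant is not positive")
  out <- curve
  out$intensity <- y / const
  out$normalization <- if (method == "unit_area") "unit_area" else "reference_point"
  out
}
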