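# moving-average smoother with end padding by the edge value
.moving_average <- function(y, width) {
  if (width <= 1) return(y)
  if (width %% 2 == 0) width <- width + 1
  k <- (width - 1) / 2
  n <- length(y)
  ypad <- c(rep(y[1], k), y, rep(y[n], k))
  out <- stats::filter(ypad, rep(1 / width, width), sides = 2)
  as.numeric(out)[(k + 1):(k + n)]
}

# resample a curve onto a common grid by linear interpolation
.resample <- function(curve, xout) {
  stats::approx(curve$abscissa, curve$intensity, xout = xout, rule = 2)$y
}

# mirror-fold an azimuthal curve about 180 degrees onto (90, 180):
# intensity(theta) averaged with intensity(360 - theta)
.fold_azimuthal <- function(curve, xout) {
  lo <- .resample(curve, xout)
  hi <- .resample(curve, 360 - xout)
  (lo + hi) / 2
}

#' Default crossing search window
#'
#' Azimuthal: (95, 175) degrees, the low side of the beam center (the two
#' sides are mirror-averaged before searching). Longitudinal:
#' (0.05, 1.5) cm. Both exclude the singular beam center and the noisy far
#' tails.
#'
#' @param direction `"azimuthal"` or `"longitudinal"`.
#' @return `c(lo, hi)`.
#' @export
default_ipl_window <- function(direction = c("azimuthal", "longitudinal")) {
  direction <- match.arg(direction)
  if (direction == "azimuthal") c(95, 175) else c(0.05, 1.5)
}

#' Locate the order-inversion crossing of two FSP curves
#'
#' Finds the position inside `window` where the difference of the two
#' curves changes sign such that the curves' relative order inverts with
#' respect to their order at the window edges; among several candidate sign
#' changes the sharpest (largest difference slope) is returned, located by
#' linear interpolation. Both curves must share direction; they are
#' resampled onto a common grid.
#'
#' @param curve_a,curve_b [fsp_curve()] objects normalized by the same
#'   method.
#' @param window `c(lo, hi)` search bounds; defaults per direction.
#' @param smooth_bins moving-average width (bins) applied before
#'   differencing; default 3 (appropriate for binned or measured curves,
#'   harmless for smooth analytic ones).
#' @return Crossing position (degrees or cm).
#' @export
find_crossing <- function(curve_a, curve_b, window = NULL, smooth_bins = 3) {
  stopifnot(inherits(curve_a, "fsp_curve"), inherits(curve_b, "fsp_curve"))
  if (curve_a$direction != curve_b$direction)
    stop("curves must share direction")
  if (is.null(window)) window <- default_ipl_window(curve_a$direction)
  grid <- sort(unique(c(curve_a$abscissa, curve_b$abscissa)))
  ya <- .moving_average(.resample(curve_a, grid), smooth_bins)
  yb <- .moving_average(.resample(curve_b, grid), smooth_bins)
  idx <- which(grid >= window[1] & grid <= window[2])
  if (length(idx) < 3) stop("window contains fewer than three grid points")
  x <- grid[idx]
  d <- ya[idx] - yb[idx]
  # exact zeros inherit the preceding sign so that a grid point sitting
  # exactly on the crossing is still detected as one sign change
  sgn <- sign(d)
  for (k in which(sgn == 0)) if (k > 1) sgn[k] <- sgn[k - 1]
  ch <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(ch) == 0) stop("no crossing inside the search window")
  slopes <- abs((d[ch + 1] - d[ch]) / (x[ch + 1] - x[ch]))
  k <- ch[which.max(slopes)]
  x[k] - d[k] * (x[k + 1] - x[k]) / (d[k + 1] - d[k])
}

#' Estimate the iso-pathlength point of a curve family
#'
#' The iso-pathlength (IPL) point is the scattering-invariant position at
#' which normalized full scattering profiles from media of different
#' reduced scattering coefficients cross. Curves are resampled to a common
#' grid, normalized to unit area over the search window, optionally
#' smoothed, and all pairwise crossings are located; the IPL estimate is
#' their mean and the spread their standard deviation. For azimuthal
#' families the two sides of the beam center are mirror-averaged before
#' the search.
#'
#' @param curves list of two or more [fsp_curve()] objects with the same
#'   direction and distinct `mu_s_reduced_label`s.
#' @param window `c(lo, hi)` search bounds; defaults per direction
#'   ([default_ipl_window()]).
#' @param smooth_bins moving-average width in bins, default 3.
#' @param normalize normalization applied before crossing detection;
#'   `"unit_area"` (over the window, the default) or `"none"` if the
#'   curves are already comparably scaled.
#' @return An object of class `ipl_estimate`: `position`, `spread`,
#'   `pair_crossings` (data frame with the two labels and crossing), `n_failed`
#'   (pairs without a crossing), `search_window`, `direction`.
#' @examples
#' geom <- cylinder_geometry(0.5)
#' fam <- theory_fsp_family("azimuthal", geom, c(22, 26, 30, 34))
#' estimate_ipl(fam)
#' @export
estimate_ipl <- function(curves, window = NULL, smooth_bins = 3,
                         normalize = c("unit_area", "none")) {
  normalize <- match.arg(normalize)
  if (!is.list(curves) || length(curves) < 2)
    stop("need at least two curves")
  lapply(curves, function(cv) stopifnot(inherits(cv, "fsp_curve")))
  direction <- curves[[1]]$direction
  if (!all(vapply(curves, function(cv) cv$direction, "") == direction))
    stop("all curves must share direction")
  if (is.null(window)) window <- default_ipl_window(direction)

  grid <- sort(unique(unlist(lapply(curves, function(cv) cv$abscissa))))
  if (direction == "azimuthal") {
    grid <- grid[grid > 90 & grid < 180]
    work <- lapply(curves, function(cv) {
      fsp_curve(grid, pmax(.fold_azimuthal(cv, grid), 0), direction,
                cv$mu_s_reduced_label, "raw")
    })
  } else {
    work <- lapply(curves, function(cv) {
      fsp_curve(grid, pmax(.resample(cv, grid), 0), direction,
                cv$mu_s_reduced_label, "raw")
    })
  }
  if (normalize == "unit_area")
    work <- lapply(work, normalize_curve, method = "unit_area",
                   window = window)

  labels <- vapply(work, function(cv) cv$mu_s_reduced_label, 0)
  m <- length(work)
  pairs <- utils::combn(m, 2)
  res <- apply(pairs, 2, function(ij) {
    tryCatch(find_crossing(work[[ij[1]]], work[[ij[2]]], window = window,
                           smooth_bins = smooth_bins),
             error = function(e) NA_real_)
  })
  ok <- !is.na(res)
  if (!any(ok)) stop("no curve pair has a crossing inside the window")
  pair_crossings <- data.frame(
    mu_s_reduced_a = labels[pairs[1, ok]],
    mu_s_reduced_b = labels[pairs[2, ok]],
    crossing = res[ok])
  structure(
    list(position = mean(res[ok]),
         spread = if (sum(ok) > 1) stats::sd(res[ok]) else 0,
         pair_crossings = pair_crossings,
         n_failed = sum(!ok),
         search_window = window,
         direction = direction),
    class = "ipl_estimate")
}

#' @export
print.ipl_estimate <- function(x, ...) {
  unit <- if (x$direction == "azimuthal") "deg" else "cm"
  cat(sprintf(
    "IPL estimate (%s): %.3g %s (spread %.2g %s, %d pair crossings%s) in window [%g, %g]\n",
    x$direction, x$position, unit, x$spread, unit,
    nrow(x$pair_crossings),
    if (x$n_failed > 0) sprintf(", %d pairs without crossing", x$n_failed) else "",
    x$search_window[1], x$search_window[2]))
  invisible(x)
}
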