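#' Longitudinal source-detector pathlengths
#'
#' Distances from the real and image positions of the major and minor
#' sources to a detector on the lumen wall at axial distance `z` from the
#' beam center (azimuth fixed at 180 degrees):
#' \eqn{l_{real} = \sqrt{z^2 + z_a^2}},
#' \eqn{l_{imag} = \sqrt{z^2 + (z_a + 2 z_b)^2}}, and the starred versions
#' with the minor-source depths.
#'
#' @param z axial distance, cm (>= 0, vectorised).
#' @param ds a [build_dual_source()] object.
#' @return List with `l_real`, `l_imag`, `l_real_minor`, `l_imag_minor` (cm).
#' @export
longitudinal_pathlengths <- function(z, ds) {
  stopifnot(inherits(ds, "dual_source_params"))
  if (any(z < 0)) stop("z must be >= 0")
  list(
    l_real = sqrt(z^2 + ds$z_a^2),
    l_imag = sqrt(z^2 + (ds$z_a + 2 * ds$z_b)^2),
    l_real_minor = sqrt(z^2 + ds$z_a_minor^2),
    l_imag_minor = sqrt(z^2 + (ds$z_a_minor + 2 * ds$z_b_minor)^2))
}

#' Azimuthal source-detector pathlengths on the curved lumen wall
#'
#' Distances from the source pair to a detector at azimuth `theta` on the
#' lumen wall (axial coordinate fixed at 0). Real sources sit outside the
#' wall at radius `r_inner + z_a`, image sources inside at
#' `r_inner - (z_a + 2 z_b)`; with the chord
#' \eqn{\rho = 2 R_0 \sin((180-\theta)/2)} this gives
#' \eqn{l_{real} = \rho \sqrt{1 + z_a^2/\rho^2 + z_a/R_0}} and
#' \eqn{l_{imag} = \rho \sqrt{1 + (z_a+2z_b)^2/\rho^2 - (z_a+2z_b)/R_0}}.
#' At theta = 180 exactly (zero chord) the longitudinal z = 0 values are
#' returned, to which these expressions converge.
#'
#' @param theta azimuth, degrees in `(0, 360)` (vectorised).
#' @param ds a [build_dual_source()] object.
#' @param r_inner lumen radius, cm.
#' @return List with `l_real`, `l_imag`, `l_real_minor`, `l_imag_minor` (cm).
#' @export
azimuthal_pathlengths <- function(theta, ds, r_inner) {
  stopifnot(inherits(ds, "dual_source_params"))
  if (any(theta <= 0 | theta >= 360)) stop("theta must be in (0, 360)")
  if ((ds$z_a + 2 * ds$z_b) >= r_inner)
    stop("image source would cross the lumen center: (z_a + 2 z_b) >= r_inner")
  rho <- chord_length(r_inner, theta)
  len1 <- function(za) {
    # source outside the wall at radius r_inner + za
    ifelse(rho > 0, sqrt(rho^2 + za^2 + za * rho^2 / r_inner), za)
  }
  len2 <- function(zi) {
    # image inside the wall at radius r_inner - zi
    ifelse(rho > 0, sqrt(rho^2 + zi^2 - zi * rho^2 / r_inner), zi)
  }
  list(
    l_real = len1(ds$z_a),
    l_imag = len2(ds$z_a + 2 * ds$z_b),
    l_real_minor = len1(ds$z_a_minor),
    l_imag_minor = len2(ds$z_a_minor + 2 * ds$z_b_minor))
}

# curvature-weighted two-source fluence shared by major/minor terms
.fluence_pair <- function(s, za, zb, l_real, l_imag, ds, r_inner) {
  if (any(l_real <= 0) || any(l_imag <= 0))
    stop("pathlengths must be positive")
  w <- (r_inner - za - 2 * zb) / (r_inner + za)
  s / (4 * pi * ds$diff_coeff) *
    (exp(-ds$mu_eff * l_real) / l_real -
       exp(-ds$mu_eff * l_imag) / l_imag * w)
}

#' Fluence rate of the major source pair
#'
#' Curvature-corrected two-source (real + image) fluence
#' \eqn{\Psi = S/(4\pi D) [e^{-\mu_{eff} l_{real}}/l_{real} -
#' e^{-\mu_{eff} l_{imag}}/l_{imag} \cdot (R_0 - z_a - 2 z_b)/(R_0 + z_a)]}.
#' The radial ratio weighting the image term is the curvature correction;
#' it tends to 1 in the planar (half-infinite) limit.
#'
#' @param lengths list with `l_real` and `l_imag` (cm), as returned by the
#'   pathlength helpers.
#' @param ds a [build_dual_source()] object.
#' @param r_inner lumen radius, cm.
#' @return Fluence, arbitrary units (vectorised).
#' @export
fluence_major <- function(lengths, ds, r_inner) {
  stopifnot(inherits(ds, "dual_source_params"))
  .fluence_pair(ds$s_major, ds$z_a, ds$z_b,
                lengths$l_real, lengths$l_imag, ds, r_inner)
}

#' Fluence rate of the minor source pair
#'
#' As [fluence_major()] with the minor-source strength, depth and lengths.
#'
#' @inheritParams fluence_major
#' @export
fluence_minor <- function(lengths, ds, r_inner) {
  stopifnot(inherits(ds, "dual_source_params"))
  .fluence_pair(ds$s_minor, ds$z_a_minor, ds$z_b_minor,
                lengths$l_real_minor, lengths$l_imag_minor, ds, r_inner)
}

#' Theoretical full scattering profile of the hollow-cylinder geometry
#'
#' Evaluates the dual-source diffusion model along the azimuthal direction
#' (detector azimuth, z = 0) or the longitudinal direction (axial distance,
#' theta = 180) and returns the total reflectance
#' \eqn{\xi [\Psi + \Psi^*]}. Constant prefactors are absorbed into the
#' normalization: curves default to `raw` and are normalized explicitly
#' before cross-curve comparison.
#'
#' @param direction `"azimuthal"` or `"longitudinal"`.
#' @param geometry a [cylinder_geometry()] object.
#' @param props an [optical_properties()] object.
#' @param grid evaluation positions: degrees in `(90, 270)` for azimuthal,
#'   cm in `[0, axial_halfwidth]` for longitudinal. Defaults to 0.5 degree /
#'   0.005 cm spacing.
#' @param n slave-index exponent, default 10.
#' @param boundary_factor extrapolated-boundary multiplier A, default 1.
#' @param literal use the paper-literal diffusion constant (default TRUE).
#' @return An [fsp_curve()] tagged with the medium's reduced scattering
#'   coefficient.
#' @examples
#' g <- cylinder_geometry(0.5)
#' p <- optical_properties_from_reduced(22, g = 0.9, mu_a = 0.1)
#' theory_fsp("azimuthal", g, p)
#' @export
theory_fsp <- function(direction = c("azimuthal", "longitudinal"),
                       geometry, props, grid = NULL, n = 10,
                       boundary_factor = 1, literal = TRUE) {
  direction <- match.arg(direction)
  stopifnot(inherits(geometry, "cylinder_geometry"),
            inherits(props, "optical_properties"))
  if (is.null(grid)) {
    grid <- if (direction == "azimuthal") {
      seq(90.5, 269.5, by = 0.5)
    } else {
      seq(0, min(geometry$axial_halfwidth, 2), by = 0.005)
    }
  }
  if (length(grid) == 0) stop("empty evaluation grid")
  if (direction == "azimuthal" && any(grid <= 90 | grid >= 270))
    stop("azimuthal grid must lie within (90, 270) degrees")
  if (direction == "longitudinal" &&
      (any(grid < 0) || any(grid > geometry$axial_halfwidth)))
    stop("longitudinal grid must lie within [0, axial_halfwidth]")
  ds <- build_dual_source(props, n = n, boundary_factor = boundary_factor,
                          literal = literal)
  lengths <- if (direction == "azimuthal") {
    azimuthal_pathlengths(grid, ds, geometry$r_inner)
  } else {
    longitudinal_pathlengths(grid, ds)
  }
  # guard the removable singularity when the minor source depth is ~0 at
  # the origin: clamp to a tiny positive length
  eps <- 1e-9
  lengths$l_real_minor <- pmax(lengths$l_real_minor, eps)
  lengths$l_real <- pmax(lengths$l_real, eps)
  intensity <- fluence_major(lengths, ds, geometry$r_inner) +
    fluence_minor(lengths, ds, geometry$r_inner)
  # far from the source on a strongly curved wall the image term can
  # slightly overshoot the real one; reflectance is clipped at zero there
  intensity <- pmax(intensity, 0)
  fsp_curve(grid, intensity, direction = direction,
            mu_s_reduced_label = props$mu_s_reduced, normalization = "raw")
}

#' Theory FSP family over several reduced scattering coefficients
#'
#' @inheritParams theory_fsp
#' @param mu_s_reduced vector of reduced scattering coefficients, 1/cm.
#' @param g scattering anisotropy shared by the family.
#' @param mu_a absorption coefficient shared by the family, 1/cm.
#' @return A list of [fsp_curve()] objects.
#' @export
theory_fsp_family <- function(direction, geometry, mu_s_reduced,
                              g = 0.9, mu_a = 0.1, grid = NULL, n = 10,
                              boundary_factor = 1, literal = TRUE) {
  lapply(mu_s_reduced, function(m) {
    theory_fsp(direction, geometry,
               optical_properties_from_reduced(m, g = g, mu_a = mu_a),
               grid = grid, n = n, boundary_factor = boundary_factor,
               literal = literal)
  })
}
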