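#' Optical properties of a turbid medium
#'
#' Bundles the absorption coefficient, scattering coefficient and scattering
#' anisotropy of one medium and derives the reduced scattering coefficient
#' \eqn{\mu_s' = \mu_s (1 - g)} and the total interaction coefficient
#' \eqn{\mu_t = \mu_a + \mu_s}.
#'
#' @param mu_a absorption coefficient, 1/cm (>= 0).
#' @param mu_s scattering coefficient, 1/cm (> 0).
#' @param g scattering anisotropy (mean cosine of the single-scattering
#'   deflection), dimensionless, in `[0, 1)`.
#' @return An object of class `optical_properties` with fields `mu_a`,
#'   `mu_s`, `g`, `mu_s_reduced` and `mu_t`.
#' @examples
#' optical_properties(mu_a = 0.1, mu_s = 220, g = 0.9)
#' @export
optical_properties <- function(mu_a, mu_s, g) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g),
            length(mu_a) == 1, length(mu_s) == 1, length(g) == 1)
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s <= 0) stop("mu_s must be > 0")
  if (g < 0 || g >= 1) stop("g must be in [0, 1)")
  structure(
    list(mu_a = mu_a, mu_s = mu_s, g = g,
         mu_s_reduced = mu_s * (1 - g),
         mu_t = mu_a + mu_s),
    class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "Optical properties: mu_a = %g /cm, mu_s = %g /cm, g = %g (mu_s' = %g /cm, mu_t = %g /cm)\n",
    x$mu_a, x$mu_s, x$g, x$mu_s_reduced, x$mu_t))
  invisible(x)
}

#' Construct optical properties from the reduced scattering coefficient
#'
#' Convenience wrapper: given \eqn{\mu_s'} and g it sets
#' \eqn{\mu_s = \mu_s' / (1 - g)}.
#'
#' @param mu_s_reduced reduced scattering coefficient, 1/cm.
#' @inheritParams optical_properties
#' @return An `optical_properties` object.
#' @export
optical_properties_from_reduced <- function(mu_s_reduced, g, mu_a = 0) {
  optical_properties(mu_a = mu_a, mu_s = mu_s_reduced / (1 - g), g = g)
}

#' Hollow-cylinder lumen geometry
#'
#' Geometry of a cylindrical air hole (lumen) surrounded by tissue: the
#' tissue occupies `r_inner <= r <= r_outer` around an axis of effectively
#' infinite length, truncated at `|y| = axial_halfwidth` for simulation.
#'
#' @param r_inner lumen radius, cm.
#' @param r_outer outer tissue radius, cm (default `r_inner + 5`).
#' @param axial_halfwidth truncation bound on the axial coordinate, cm.
#' @return An object of class `cylinder_geometry`.
#' @export
cylinder_geometry <- function(r_inner, r_outer = r_inner + 5,
                              axial_halfwidth = 5) {
  stopifnot(is.numeric(r_inner), is.numeric(r_outer),
            is.numeric(axial_halfwidth))
  if (r_inner <= 0) stop("r_inner must be > 0")
  if (r_outer <= r_inner) stop("r_outer must exceed r_inner")
  if (axial_halfwidth <= 0) stop("axial_halfwidth must be > 0")
  structure(
    list(r_inner = r_inner, r_outer = r_outer,
         axial_halfwidth = axial_halfwidth),
    class = "cylinder_geometry")
}

#' Lumen diameter
#' @param geometry a [cylinder_geometry()] object.
#' @return `2 * r_inner`, cm.
#' @export
diameter <- function(geometry) {
  stopifnot(inherits(geometry, "cylinder_geometry"))
  2 * geometry$r_inner
}

#' Slave-source index
#'
#' The weight \eqn{\eta = [g \exp(1 - g)]^{1/n}} carried by the minor
#' (slave) isotropic source of the dual-source representation of a pencil
#' beam near its point of entry. Equals 1 for fully forward scattering
#' (g = 1) and 0 for isotropic scattering (g = 0).
#'
#' @param g scattering anisotropy in `[0, 1]`.
#' @param n open model exponent (> 0), default 10.
#' @return eta, dimensionless, in `[0, 1]`.
#' @examples
#' slave_index(0.9)
#' @export
slave_index <- function(g, n = 10) {
  if (any(g < 0 | g > 1)) stop("g must be in [0, 1]")
  if (n <= 0) stop("n must be > 0")
  (g * exp(1 - g))^(1 / n)
}

#' Diffusion constant and effective attenuation coefficient
#'
#' Two conventions are supported. The default (`literal = TRUE`) takes
#' \eqn{D = 1/(\mu_a + \mu_s')}; the standard diffusion convention
#' (`literal = FALSE`) takes \eqn{D = 1/(3 (\mu_a + \mu_s'))}. In both
#' cases \eqn{\mu_{eff} = \sqrt{\mu_a / D}}, the only dimensionally
#' consistent form (1/cm).
#'
#' @param props an [optical_properties()] object.
#' @param literal use the `1/(mu_a + mu_s')` convention for D (default);
#'   `FALSE` selects the standard factor-3 convention.
#' @return A list with `diff_coeff` (cm) and `mu_eff` (1/cm).
#' @examples
#' diffusion_constants(optical_properties(0.25, 160, 0.9))
#' @export
diffusion_constants <- function(props, literal = TRUE) {
  stopifnot(inherits(props, "optical_properties"))
  if (props$mu_s_reduced <= 0) stop("mu_s_reduced must be > 0")
  denom <- props$mu_a + props$mu_s_reduced
  D <- if (literal) 1 / denom else 1 / (3 * denom)
  list(diff_coeff = D, mu_eff = sqrt(props$mu_a / D))
}

#' Dual-source parameters for the near-point-of-entry diffusion model
#'
#' Builds the major/minor isotropic source pair replacing a pencil beam:
#' the major real source at depth \eqn{R_a = 1/\mu_s'} with strength S, and
#' a shallow minor (slave) source at depth `minor_depth_rule(Ra, eta)`
#' (default \eqn{(1 - \eta) R_a}) with strength
#' \eqn{S^* = S \eta \exp(-\mu_{eff} (R_a + R_a^*)/2)}. Image sources sit
#' beyond the extrapolated boundary at distance
#' \eqn{z_b = 2 A D} from the physical boundary.
#'
#' @inheritParams diffusion_constants
#' @param n slave-index exponent, default 10.
#' @param boundary_factor extrapolated-boundary multiplier A in
#'   `z_b = 2 * A * D`, default 1 (matched boundary).
#' @param s_major strength of the major source (arbitrary units).
#' @param minor_depth_rule function of `(ra_major, eta)` returning the
#'   minor-source depth in cm; pluggable so alternative readings of the
#'   minor-depth relation can be swapped in.
#' @return An object of class `dual_source_params` with fields `ra_major`,
#'   `ra_minor`, `eta`, `n_exponent`, `s_major`, `s_minor`, `diff_coeff`,
#'   `mu_eff`, `z_a`, `z_b`, `z_a_minor`, `z_b_minor`, `boundary_factor`.
#' @examples
#' build_dual_source(optical_properties(0, 160, 0.9))
#' @export
build_dual_source <- function(props, n = 10, boundary_factor = 1,
                              literal = TRUE, s_major = 1,
                              minor_depth_rule = function(ra, eta) (1 - eta) * ra) {
  stopifnot(inherits(props, "optical_properties"))
  dc <- diffusion_constants(props, literal = literal)
  ra <- 1 / props$mu_s_reduced
  eta <- slave_index(props$g, n)
  ra_minor <- minor_depth_rule(ra, eta)
  if (ra_minor < 0) stop("minor-source depth must be >= 0")
  s_minor <- s_major * eta * exp(-dc$mu_eff * (ra + ra_minor) / 2)
  zb <- 2 * boundary_factor * dc$diff_coeff
  structure(
    list(ra_major = ra, ra_minor = ra_minor, eta = eta, n_exponent = n,
         s_major = s_major, s_minor = s_minor,
         diff_coeff = dc$diff_coeff, mu_eff = dc$mu_eff,
         z_a = ra, z_b = zb, z_a_minor = ra_minor, z_b_minor = zb,
         boundary_factor = boundary_factor),
    class = "dual_source_params")
}

#' @export
print.dual_source_params <- function(x, ...) {
  cat(sprintf(
    paste0("Dual-source parameters:\n",
           "  major: depth %.4g cm, strength %.4g\n",
           "  minor: depth %.4g cm, strength %.4g (eta = %.5g)\n",
           "  D = %.4g cm, mu_eff = %.4g /cm, z_b = %.4g cm (A = %g)\n"),
    x$ra_major, x$s_major, x$ra_minor, x$s_minor, x$eta,
    x$diff_coeff, x$mu_eff, x$z_b, x$boundary_factor))
  invisible(x)
}

#' Chord (line-of-sight) length across the lumen
#'
#' Straight-line distance between two points on the lumen wall separated by
#' azimuth `theta` from the beam center at 180 degrees:
#' \eqn{\rho = 2 R_0 \sin((180 - \theta)/2)}. Symmetric about theta = 180.
#'
#' @param r_inner lumen radius, cm.
#' @param theta azimuth, degrees in `[0, 360]` (beam center at 180).
#' @return chord length rho, cm (vectorised over `theta`).
#' @examples
#' chord_length(0.5, 144)
#' @export
chord_length <- function(r_inner, theta) {
  if (any(theta < 0 | theta > 360)) stop("theta must be in [0, 360]")
  if (r_inner <= 0) stop("r_inner must be > 0")
  2 * r_inner * abs(sin((180 - theta) / 2 * pi / 180))
}
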