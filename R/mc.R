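#' Monte Carlo configuration
#'
#' Settings for photon transport in tissue surrounding a cylindrical air
#' hole. Photons launch at a point on the lumen wall heading radially into
#' the tissue; exit positions back into the lumen are tallied by azimuth
#' (entry point at 180 degrees) and axial distance.
#'
#' @param geometry a [cylinder_geometry()] object.
#' @param props an [optical_properties()] object. Absorption defaults to
#'   being carried as a pathlength weight `exp(-mu_a * L)` at exit; set
#'   `mu_a = 0` (the default study condition) for unit weights.
#' @param n_photons number of photons, default 1e6.
#' @param seed integer seed; identical (seed, config) pairs give
#'   bit-identical tallies.
#' @param azimuthal_bin azimuth bin width, degrees (default 2).
#' @param axial_bin axial bin width, cm (default 0.02).
#' @param azimuthal_band half-width in `|y|` (cm) of the band used for the
#'   azimuthal tally (default 0.05).
#' @param longitudinal_band half-width in degrees around 180 of the band
#'   used for the longitudinal tally (default 5).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(geometry, props, n_photons = 1e6, seed = 1,
                      azimuthal_bin = 2, axial_bin = 0.02,
                      azimuthal_band = 0.05, longitudinal_band = 5) {
  stopifnot(inherits(geometry, "cylinder_geometry"),
            inherits(props, "optical_properties"))
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (azimuthal_bin <= 0 || axial_bin <= 0 ||
      azimuthal_band <= 0 || longitudinal_band <= 0)
    stop("bins and bands must be positive")
  structure(
    list(geometry = geometry, props = props,
         n_photons = as.numeric(n_photons), seed = as.integer(seed),
         azimuthal_bin = azimuthal_bin, axial_bin = axial_bin,
         azimuthal_band = azimuthal_band,
         longitudinal_band = longitudinal_band),
    class = "mc_config")
}

#' Sample a free-flight step length
#'
#' Exponential step between interaction events:
#' `step = -log(u) / mu_t`.
#'
#' @param mu_t total interaction coefficient, 1/cm (> 0).
#' @param u uniform(0, 1) deviates (vectorised).
#' @return Step lengths, cm.
#' @export
sample_step <- function(mu_t, u) {
  if (mu_t <= 0) stop("mu_t must be > 0")
  if (any(u <= 0 | u >= 1)) stop("u must lie in (0, 1)")
  -log(u) / mu_t
}

#' Sample the Henyey-Greenstein scattering-angle cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function: for
#' `g > 0`, `cos = (1 + g^2 - ((1 - g^2)/(1 - g + 2 g u))^2) / (2 g)`;
#' for `g = 0` the cosine is uniform on `[-1, 1]`.
#'
#' @param g anisotropy in `[0, 1)`.
#' @param u uniform(0, 1) deviates (vectorised).
#' @return Cosines in `[-1, 1]`.
#' @export
sample_hg_cosine <- function(g, u) {
  if (g < 0 || g >= 1) stop("g must be in [0, 1)")
  if (g == 0) return(2 * u - 1)
  tmp <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - tmp^2) / (2 * g)))
}

#' Deflect a direction vector by a scattering event
#'
#' Standard local-frame rotation of a unit direction by polar angle
#' `acos(cos_theta)` and azimuthal scatter angle `psi`, special-cased near
#' `|uz| = 1`.
#'
#' @param direction unit 3-vector `(ux, uy, uz)`.
#' @param cos_theta cosine of the polar deflection.
#' @param psi azimuthal scatter angle, radians in `[0, 2*pi)`.
#' @return New unit 3-vector.
#' @export
deflect <- function(direction, cos_theta, psi) {
  stopifnot(length(direction) == 3)
  ct <- cos_theta
  st <- sqrt(max(0, 1 - ct^2))
  ux <- direction[1]; uy <- direction[2]; uz <- direction[3]
  if (abs(uz) > 0.99999) {
    new <- c(st * cos(psi), st * sin(psi), ct * sign(uz))
  } else {
    den <- sqrt(1 - uz^2)
    new <- c(
      st * (ux * uz * cos(psi) - uy * sin(psi)) / den + ux * ct,
      st * (uy * uz * cos(psi) + ux * sin(psi)) / den + uy * ct,
      -st * cos(psi) * den + uz * ct)
  }
  new / sqrt(sum(new^2))
}

#' First crossing of a photon segment into the lumen
#'
#' Solves the quadratic for the segment `p0 + t * dir`, `0 < t <= step`,
#' against the infinite cylinder `x^2 + z^2 = r_inner^2` and returns the
#' first crossing into the lumen, if any.
#'
#' @param p0 photon position `(x, y, z)`, cm; must lie in the tissue
#'   (`sqrt(x^2 + z^2) >= r_inner - 1e-12`).
#' @param dir unit direction 3-vector.
#' @param step segment length, cm.
#' @param r_inner lumen radius, cm.
#' @return `NULL` if the segment does not reach the lumen, else a list with
#'   `hit_point` (3-vector) and `distance` (cm).
#' @export
intersect_lumen <- function(p0, dir, step, r_inner) {
  stopifnot(length(p0) == 3, length(dir) == 3)
  if (sqrt(p0[1]^2 + p0[3]^2) < r_inner - 1e-12)
    stop("photon must start in the tissue")
  a <- dir[1]^2 + dir[3]^2
  b <- 2 * (p0[1] * dir[1] + p0[3] * dir[3])
  cc <- p0[1]^2 + p0[3]^2 - r_inner^2
  if (a <= 0 || b >= 0) return(NULL)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NULL)
  t1 <- (-b - sqrt(disc)) / (2 * a)
  if (t1 <= 0 || t1 > step) return(NULL)
  list(hit_point = p0 + t1 * dir, distance = t1)
}

#' Propagate a single photon (reference implementation)
#'
#' Pure-R transport loop used as the reference for the compiled simulator:
#' alternating exponential steps, lumen-intersection checks and
#' Henyey-Greenstein scattering, from launch at `(0, 0, r_inner)` with
#' direction `(0, 0, 1)` until the photon re-enters the lumen (detected),
#' crosses the outer radius, or leaves the axial truncation bound. Draws
#' its deviates from R's RNG.
#'
#' @param config an [mc_config()] object.
#' @return A list: `status` (`"detected"`, `"lost_outer"`, `"lost_axial"`),
#'   and for detections `exit_azimuth` (degrees, entry at 180), `exit_y`
#'   (cm) and `weight`.
#' @export
propagate <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  geom <- config$geometry
  props <- config$props
  p <- c(0, 0, geom$r_inner)
  dir <- c(0, 0, 1)
  path <- 0
  first <- TRUE
  repeat {
    s <- sample_step(props$mu_t, stats::runif(1))
    if (!first) {
      hit <- intersect_lumen(p, dir, s, geom$r_inner)
      if (!is.null(hit)) {
        path <- path + hit$distance
        phi <- 180 + atan2(hit$hit_point[1], hit$hit_point[3]) * 180 / pi
        w <- if (props$mu_a > 0) exp(-props$mu_a * path) else 1
        return(list(status = "detected", exit_azimuth = phi,
                    exit_y = hit$hit_point[2], weight = w))
      }
    }
    p <- p + s * dir
    path <- path + s
    first <- FALSE
    if (any(!is.finite(p))) stop("non-finite photon state")
    if (p[1]^2 + p[3]^2 >= geom$r_outer^2)
      return(list(status = "lost_outer"))
    if (abs(p[2]) >= geom$axial_halfwidth)
      return(list(status = "lost_axial"))
    ct <- sample_hg_cosine(props$g, stats::runif(1))
    psi <- 2 * pi * stats::runif(1)
    dir <- deflect(dir, ct, psi)
  }
}

#' Run the hollow-cylinder Monte Carlo simulation
#'
#' Compiled photon-transport loop. Detected photons are tallied into an
#' azimuthal histogram (2-degree bins over (90, 270), restricted to exits
#' with `|y| <= azimuthal_band`) and a longitudinal histogram (`|y|` bins,
#' restricted to exits within `longitudinal_band` degrees of the entry
#' azimuth). Deterministic given `(seed, config)`.
#'
#' @param config an [mc_config()] object.
#' @param keep_records keep per-photon exit records (up to `max_records`).
#' @param max_records cap on stored exit records.
#' @return A list of class `mc_result` with components `tally` (class
#'   `detection_tally`: histograms and loss counts), `azimuthal` and
#'   `longitudinal` ([fsp_curve()] objects labelled with the medium's
#'   mu_s'), and optionally `records`.
#' @examples
#' cfg <- mc_config(cylinder_geometry(0.5),
#'                  optical_properties_from_reduced(16, g = 0.9),
#'                  n_photons = 1e4, seed = 7)
#' run_simulation(cfg)
#' @export
run_simulation <- function(config, keep_records = FALSE, max_records = 1e6) {
  stopifnot(inherits(config, "mc_config"))
  geom <- config$geometry
  props <- config$props
  raw <- .mc_run_cpp(config$n_photons, config$seed,
                     geom$r_inner, geom$r_outer, geom$axial_halfwidth,
                     props$mu_a, props$mu_s, props$g,
                     config$azimuthal_bin, config$axial_bin,
                     config$azimuthal_band, config$longitudinal_band,
                     keep_records, as.integer(max_records))
  if (raw$n_detected == 0)
    stop("no photons detected; increase n_photons or check geometry")
  az_centers <- 90 + (seq_along(raw$az_hist) - 0.5) * config$azimuthal_bin
  ax_centers <- (seq_along(raw$ax_hist) - 0.5) * config$axial_bin
  az_full_centers <- (seq_along(raw$az_full) - 0.5) * config$azimuthal_bin
  tally <- structure(
    list(azimuthal_hist = raw$az_full, azimuthal_centers = az_full_centers,
         longitudinal_hist = raw$ax_full, longitudinal_centers = ax_centers,
         n_detected = raw$n_detected, n_lost_outer = raw$n_lost_outer,
         n_lost_axial = raw$n_lost_axial, n_photons = config$n_photons,
         total_steps = raw$total_steps),
    class = "detection_tally")
  out <- list(
    tally = tally,
    azimuthal = fsp_curve(az_centers, raw$az_hist, "azimuthal",
                          props$mu_s_reduced, "raw"),
    longitudinal = fsp_curve(ax_centers, raw$ax_hist, "longitudinal",
                             props$mu_s_reduced, "raw"))
  if (keep_records)
    out$records <- data.frame(exit_azimuth = raw$exit_azimuth,
                              exit_y = raw$exit_y, weight = raw$weight)
  class(out) <- "mc_result"
  out
}

#' @export
print.detection_tally <- function(x, ...) {
  cat(sprintf(
    "Detection tally: %d photons -> %d detected, %d lost (outer), %d lost (axial)\n",
    as.integer(x$n_photons), as.integer(x$n_detected),
    as.integer(x$n_lost_outer), as.integer(x$n_lost_axial)))
  invisible(x)
}

#' @export
print.mc_result <- function(x, ...) {
  print(x$tally)
  cat(sprintf("  azimuthal tally weight %g, longitudinal tally weight %g\n",
              sum(x$tally$azimuthal_hist), sum(x$tally$longitudinal_hist)))
  invisible(x)
}

#' Monte Carlo FSP family over several scattering coefficients
#'
#' Runs one simulation per `mu_s` value (seeds `seed`, `seed + 1`, ...)
#' and collects azimuthal and longitudinal curve families. The scattering
#' coefficients are used directly as the interaction-coefficient scale of
#' the transport (`mu_t = mu_a + mu_s`), with the Henyey-Greenstein
#' anisotropy applied at each scatter. Curves are labelled with the given
#' `mu_s` values and are on the counts-per-launched-photon scale, which is
#' common (energy-conserving) across the family: compare them with
#' `estimate_ipl(..., normalize = "none")`.
#'
#' @param geometry a [cylinder_geometry()] object.
#' @param mu_s vector of scattering coefficients, 1/cm.
#' @param g anisotropy shared by the family, default 0.9.
#' @param mu_a absorption coefficient, default 0 (absorption neglected; the
#'   study condition for locating the scattering-invariant point).
#' @param n_photons photons per medium.
#' @param seed base seed.
#' @param ... further arguments to [mc_config()].
#' @return List with `azimuthal` and `longitudinal` (lists of
#'   [fsp_curve()]) and `tallies`.
#' @export
mc_fsp_family <- function(geometry, mu_s, g = 0.9, mu_a = 0,
                          n_photons = 1e6, seed = 1, ...) {
  runs <- lapply(seq_along(mu_s), function(i) {
    props <- optical_properties(mu_a = mu_a, mu_s = mu_s[i], g = g)
    cfg <- mc_config(geometry, props, n_photons = n_photons,
                     seed = seed + i - 1L, ...)
    out <- run_simulation(cfg)
    out$azimuthal$intensity <- out$azimuthal$intensity / n_photons
    out$longitudinal$intensity <- out$longitudinal$intensity / n_photons
    out$azimuthal$mu_s_reduced_label <- mu_s[i]
    out$longitudinal$mu_s_reduced_label <- mu_s[i]
    out
  })
  list(azimuthal = lapply(runs, `[[`, "azimuthal"),
       longitudinal = lapply(runs, `[[`, "longitudinal"),
       tallies = lapply(runs, `[[`, "tally"))
}
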