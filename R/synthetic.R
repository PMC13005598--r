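#' Construct a curve family with an exact common crossing
#'
#' Builds `n_curves` smooth positive profiles over `domain` whose unique
#' pairwise crossing, after unit-area normalization over the analysis
#' `window`, sits exactly at `position`. The family consists of convex
#' mixtures of two window-normalized exponential decays in the distance
#' from the beam center; the second decay rate is solved (by root finding)
#' so that the two basis shapes cross at `position`. Every pair then
#' crosses exactly there, so [estimate_ipl()] recovers `position` with
#' zero spread by construction.
#'
#' @param position crossing position: degrees (azimuthal, low side of the
#'   180-degree beam center) or cm (longitudinal).
#' @param n_curves number of curves (>= 2).
#' @param domain `c(lo, hi)` curve domain; defaults to (90.5, 269.5)
#'   degrees / (0.0025, 2) cm.
#' @param direction `"azimuthal"` or `"longitudinal"`.
#' @param spacing grid spacing (degrees or cm).
#' @param window unit-area window; defaults to [default_ipl_window()].
#' @param base_rate decay rate of the slowest basis shape (1/deg or 1/cm);
#'   defaults to `0.5 / distance(position, beam center)`.
#' @return List of [fsp_curve()] objects with pseudo mu_s' labels `1..n`
#'   ordered from shallow to steep decay.
#' @examples
#' fam <- make_crossing_family(150, 4)
#' estimate_ipl(fam)$position
#' @export
make_crossing_family <- function(position, n_curves,
                                 domain = NULL,
                                 direction = c("azimuthal", "longitudinal"),
                                 spacing = NULL, window = NULL,
                                 base_rate = NULL) {
  direction <- match.arg(direction)
  if (n_curves < 2) stop("need at least two curves")
  if (is.null(domain))
    domain <- if (direction == "azimuthal") c(90.5, 269.5) else c(0.0025, 2)
  if (diff(domain) <= 0) stop("degenerate domain")
  if (is.null(spacing))
    spacing <- if (direction == "azimuthal") 0.5 else 0.005
  if (is.null(window)) window <- default_ipl_window(direction)
  x <- seq(domain[1], domain[2], by = spacing)
  d <- if (direction == "azimuthal") abs(x - 180) else x
  dstar <- if (direction == "azimuthal") 180 - position else position
  if (dstar <= 0) stop("position must lie on the low side of the center")
  win_d <- if (direction == "azimuthal") sort(180 - window) else window
  if (dstar <= win_d[1] || dstar >= win_d[2])
    stop("position must lie strictly inside the analysis window")
  # window integral of exp(-k d) (continuous form)
  wint <- function(k) (exp(-k * win_d[1]) - exp(-k * win_d[2])) / k
  # crossing distance of the two window-normalized exponentials
  cross_of <- function(k1, k2) log(wint(k1) / wint(k2)) / (k2 - k1)
  # candidate base rates: decaying bases put the crossing below the window
  # centroid, growing bases (negative rate) above it
  wlen <- diff(win_d)
  k1_ladder <- if (is.null(base_rate)) {
    c(0.5 / dstar, 0.25 / dstar, 0.1 / dstar,
      -1 / wlen, -2 / wlen, -4 / wlen, -8 / wlen)
  } else {
    base_rate
  }
  k2 <- NULL
  for (k1 in k1_ladder) {
    f <- function(k2) cross_of(k1, k2) - dstar
    hi <- abs(k1) + 50 / dstar
    eps <- abs(k1) * 1e-4 + 1e-9
    if (f(k1 + eps) > 0 && f(hi) < 0) {
      k2 <- stats::uniroot(f, c(k1 + eps, hi), tol = 1e-12)$root
      break
    }
  }
  if (is.null(k2))
    stop("could not place the crossing at the requested position")
  u <- exp(-k1 * d) / wint(k1)
  v <- exp(-k2 * d) / wint(k2)
  lambda <- seq(0, 1, length.out = n_curves)
  lapply(seq_len(n_curves), function(i) {
    y <- (1 - lambda[i]) * u + lambda[i] * v
    fsp_curve(x, y, direction = direction,
              mu_s_reduced_label = i, normalization = "raw")
  })
}

#' Specification of a rendered synthetic endoscope frame
#'
#' @param truth_curve an [fsp_curve()] providing the ground-truth decay.
#' @param view `"longitudinal"` or `"azimuthal"`.
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param gsd cm per pixel.
#' @param poisson_scale photons per intensity unit for shot noise (0
#'   disables).
#' @param gaussian_read_sd additive read-noise standard deviation in
#'   intensity units (0 disables).
#' @param seed integer seed; identical spec + seed give identical frames.
#' @param beam_sigma_rows cross-row Gaussian falloff (longitudinal view),
#'   pixels.
#' @param ring_radius_px ring radius (azimuthal view), pixels.
#' @param ring_sigma_px radial Gaussian half-width of the ring, pixels.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(truth_curve, view = c("longitudinal", "azimuthal"),
                        frame_shape = c(201, 201), gsd = 0.01,
                        poisson_scale = 0, gaussian_read_sd = 0,
                        seed = 1, beam_sigma_rows = 6,
                        ring_radius_px = NULL, ring_sigma_px = 4) {
  view <- match.arg(view)
  stopifnot(inherits(truth_curve, "fsp_curve"))
  if (poisson_scale < 0 || gaussian_read_sd < 0)
    stop("noise parameters must be >= 0")
  if (is.null(ring_radius_px))
    ring_radius_px <- floor(min(frame_shape) * 0.35)
  structure(
    list(truth_curve = truth_curve, view = view, frame_shape = frame_shape,
         gsd = gsd, poisson_scale = poisson_scale,
         gaussian_read_sd = gaussian_read_sd, seed = as.integer(seed),
         beam_sigma_rows = beam_sigma_rows,
         ring_radius_px = ring_radius_px, ring_sigma_px = ring_sigma_px),
    class = "render_spec")
}

#' Render a synthetic endoscope frame from a ground-truth curve
#'
#' Longitudinal view: the intensity along each row follows the truth curve
#' in the distance from the center column (cm via the gsd), modulated by a
#' Gaussian falloff across rows around the beam row. Azimuthal view: an
#' annular ring around the frame center whose angular intensity follows the
#' truth curve (beam center at 180 degrees placed at the top of the
#' frame). Poisson shot noise is applied first, then Gaussian read noise;
#' output is deterministic for a fixed spec.
#'
#' @param spec a [render_spec()].
#' @return An [endoscope_frame()].
#' @export
render_frame <- function(spec) {
  stopifnot(inherits(spec, "render_spec"))
  tc <- spec$truth_curve
  nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  truth_at <- function(d) {
    stats::approx(tc$abscissa, tc$intensity, xout = d, rule = 2)$y
  }
  if (spec$view == "longitudinal") {
    d_cm <- abs(col(matrix(0, nr, nc)) - ctr[2]) * spec$gsd
    if (max(d_cm) > max(tc$abscissa) + spec$gsd)
      stop("truth curve domain smaller than the frame extent")
    prof <- matrix(truth_at(d_cm), nr, nc)
    falloff <- exp(-((row(prof) - ctr[1])^2) / (2 * spec$beam_sigma_rows^2))
    img <- prof * falloff
  } else {
    rr <- row(matrix(0, nr, nc)) - ctr[1]
    cc <- col(matrix(0, nr, nc)) - ctr[2]
    rad <- sqrt(rr^2 + cc^2)
    ang <- (atan2(cc, -rr) * 180 / pi) %% 360  # 0 at top of frame
    # beam center (truth 180 deg) at the top: shift so top maps to 180
    theta <- (ang + 180) %% 360
    theta[theta < min(tc$abscissa)] <- min(tc$abscissa)
    theta[theta > max(tc$abscissa)] <- max(tc$abscissa)
    ringprof <- exp(-((rad - spec$ring_radius_px)^2) /
                      (2 * spec$ring_sigma_px^2))
    img <- truth_at(theta) * ringprof
    dim(img) <- c(nr, nc)
  }
  set.seed(spec$seed)
  if (spec$poisson_scale > 0)
    img <- stats::rpois(length(img), img * spec$poisson_scale) /
      spec$poisson_scale
  if (spec$gaussian_read_sd > 0)
    img <- img + stats::rnorm(length(img), sd = spec$gaussian_read_sd)
  img <- pmax(img, 0)
  dim(img) <- c(nr, nc)
  endoscope_frame(img, gsd = spec$gsd, view = spec$view)
}

#' Synthetic three-sample absorption workflow
#'
#' Emulates the self-calibration measurement: a negligible-absorption
#' reference, a calibrator of known absorption, and an unknown sample, all
#' measured at the IPL angle of a lumen of the given diameter. Intensities
#' obey `I = I0 * exp(-mu_a * DPF0 * L)` with multiplicative lognormal
#' noise.
#'
#' @param mu_a_truth absorption coefficient of the unknown sample, 1/cm.
#' @param dpf0_truth zero-absorption differential pathlength factor.
#' @param diameter lumen diameter, cm.
#' @param theta_ipl IPL angle, degrees.
#' @param noise_sd lognormal sigma of the multiplicative intensity noise.
#' @param n_rep number of replicate triples.
#' @param seed integer seed.
#' @param mu_a_calibrator known absorption of the calibrator, 1/cm
#'   (default 0.25, a hemoglobin phantom at 633 nm).
#' @param i0 noise-free reference intensity (arbitrary units).
#' @return A data frame with columns `i_ref`, `i_cal`, `i_unknown`, one row
#'   per replicate, with the generating truths attached as attributes
#'   `mu_a_truth`, `dpf0_truth`, `mu_a_calibrator`, `arc_length`.
#' @export
make_absorption_study <- function(mu_a_truth, dpf0_truth, diameter,
                                  theta_ipl, noise_sd = 0.02, n_rep = 1,
                                  seed = 1, mu_a_calibrator = 0.25,
                                  i0 = 1000) {
  if (mu_a_truth < 0 || dpf0_truth <= 0 || diameter <= 0 ||
      mu_a_calibrator <= 0 || noise_sd < 0 || n_rep < 1)
    stop("parameters must be positive (mu_a_truth >= 0)")
  L <- arc_length(diameter, theta_ipl)
  set.seed(seed)
  noise <- function() {
    if (noise_sd == 0) rep(1, n_rep)
    else exp(stats::rnorm(n_rep, mean = 0, sd = noise_sd))
  }
  out <- data.frame(
    i_ref = i0 * noise(),
    i_cal = i0 * exp(-mu_a_calibrator * dpf0_truth * L) * noise(),
    i_unknown = i0 * exp(-mu_a_truth * dpf0_truth * L) * noise())
  attr(out, "mu_a_truth") <- mu_a_truth
  attr(out, "dpf0_truth") <- dpf0_truth
  attr(out, "mu_a_calibrator") <- mu_a_calibrator
  attr(out, "arc_length") <- L
  attr(out, "theta_ipl") <- theta_ipl
  attr(out, "diameter") <- diameter
  out
}

#' Recover the unknown absorption from a three-sample study
#'
#' Applies the full self-calibration chain to each replicate of a
#' [make_absorption_study()] table: DPF0 from the calibrator/reference
#' pair, then the unknown's absorption from the reference and the
#' calibrated DPF0.
#'
#' @param study data frame from [make_absorption_study()].
#' @return Numeric vector of recovered absorption coefficients, 1/cm (one
#'   per replicate).
#' @export
recover_absorption <- function(study) {
  th <- attr(study, "theta_ipl"); dia <- attr(study, "diameter")
  mu_cal <- attr(study, "mu_a_calibrator")
  vapply(seq_len(nrow(study)), function(i) {
    d0 <- dpf0_from_reference(study$i_cal[i], study$i_ref[i], mu_cal,
                              dia, th)
    mu_a_from_dpf0(study$i_unknown[i], study$i_ref[i], d0, dia, th)
  }, 0)
}
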