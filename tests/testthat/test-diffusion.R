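ds_fixture <- function(mu_a = 0.1, mus = 160, g = 0.9, ...) {
  build_dual_source(optical_properties(mu_a, mus, g), ...)
}

test_that("longitudinal pathlengths are the Pythagorean distances", {
  ds <- ds_fixture()
  # on-axis values collapse to the source depths
  l0 <- longitudinal_pathlengths(0, ds)
  expect_equal(l0$l_real, ds$z_a)
  expect_equal(l0$l_imag, ds$z_a + 2 * ds$z_b)
  expect_equal(l0$l_real_minor, ds$z_a_minor)
  # hand-checked Pythagoras with za = 0.0625, zb = 2 * D
  z <- 0.4
  l <- longitudinal_pathlengths(z, ds)
  expect_equal(l$l_real, sqrt(z^2 + ds$z_a^2))
  expect_equal(l$l_imag, sqrt(z^2 + (ds$z_a + 2 * ds$z_b)^2))
  # far-field limit: image and real lengths converge
  lf <- longitudinal_pathlengths(1e5, ds)
  expect_equal(lf$l_imag / lf$l_real, 1, tolerance = 1e-8)
  expect_error(longitudinal_pathlengths(-0.1, ds), "z")
})

test_that("azimuthal pathlengths agree with a law-of-cosines oracle", {
  ds <- ds_fixture()
  r0 <- 0.5
  for (th in c(100, 144, 170, 210, 250)) {
    l <- azimuthal_pathlengths(th, ds, r0)
    delta <- (180 - th) * pi / 180
    # real source at radius r0 + za, detector on the wall at angle delta
    d_oracle <- sqrt((r0 + ds$z_a)^2 + r0^2 -
                       2 * r0 * (r0 + ds$z_a) * cos(delta))
    expect_equal(l$l_real, d_oracle, tolerance = 1e-12)
    # image source at radius r0 - (za + 2 zb)
    zi <- ds$z_a + 2 * ds$z_b
    d_img <- sqrt((r0 - zi)^2 + r0^2 - 2 * r0 * (r0 - zi) * cos(delta))
    expect_equal(l$l_imag, d_img, tolerance = 1e-12)
  }
})

test_that("azimuthal pathlengths: beam-center and planar limits", {
  ds <- ds_fixture()
  l <- azimuthal_pathlengths(180, ds, 0.5)
  expect_equal(l$l_real, ds$z_a)
  expect_equal(l$l_imag, ds$z_a + 2 * ds$z_b)
  # huge radius: half-infinite geometry, l_real -> sqrt(rho^2 + za^2)
  r_big <- 1e6
  th <- 179.9999  # small chord
  rho <- chord_length(r_big, th)
  lb <- azimuthal_pathlengths(th, ds, r_big)
  expect_equal(lb$l_real, sqrt(rho^2 + ds$z_a^2), tolerance = 1e-6)
  # image source deeper than the lumen radius is a geometry error
  expect_error(azimuthal_pathlengths(144, ds, ds$z_a + 2 * ds$z_b),
               "lumen")
})

test_that("fluence terms are linear in source strength and planar limit", {
  p <- optical_properties(0.1, 160, 0.9)
  ds2 <- build_dual_source(p, s_major = 2)
  ds1 <- build_dual_source(p, s_major = 1)
  r0 <- 0.5
  lg <- azimuthal_pathlengths(150, ds1, r0)
  expect_equal(fluence_major(lg, ds2, r0), 2 * fluence_major(lg, ds1, r0))
  # independent direct evaluation of the curvature-weighted two-source form
  w <- (r0 - ds1$z_a - 2 * ds1$z_b) / (r0 + ds1$z_a)
  direct <- ds1$s_major / (4 * pi * ds1$diff_coeff) *
    (exp(-ds1$mu_eff * lg$l_real) / lg$l_real -
       exp(-ds1$mu_eff * lg$l_imag) / lg$l_imag * w)
  expect_equal(fluence_major(lg, ds1, r0), direct)
  # planar limit: weight -> 1 recovers the semi-infinite two-source form
  r_big <- 1e8
  semi <- ds1$s_major / (4 * pi * ds1$diff_coeff) *
    (exp(-ds1$mu_eff * lg$l_real) / lg$l_real -
       exp(-ds1$mu_eff * lg$l_imag) / lg$l_imag)
  expect_equal(fluence_major(lg, ds1, r_big), semi, tolerance = 1e-7)
  expect_error(fluence_major(list(l_real = -1, l_imag = 1), ds1, r0),
               "positive")
})

test_that("minor fluence vanishes with eta and mirrors the major form", {
  # isotropic scattering: eta = 0, minor source off
  ds0 <- build_dual_source(optical_properties(0.1, 16, 0))
  lg <- longitudinal_pathlengths(0.3, ds0)
  expect_equal(fluence_minor(lg, ds0, 0.5), 0)
  # generic parameters match the direct evaluation
  ds <- ds_fixture()
  lg <- longitudinal_pathlengths(0.3, ds)
  w <- (0.5 - ds$z_a_minor - 2 * ds$z_b_minor) / (0.5 + ds$z_a_minor)
  direct <- ds$s_minor / (4 * pi * ds$diff_coeff) *
    (exp(-ds$mu_eff * lg$l_real_minor) / lg$l_real_minor -
       exp(-ds$mu_eff * lg$l_imag_minor) / lg$l_imag_minor * w)
  expect_equal(fluence_minor(lg, ds, 0.5), direct)
})

test_that("theory FSP is symmetric about the beam center and scale-free", {
  geom <- cylinder_geometry(0.5)
  p <- optical_properties_from_reduced(22, g = 0.9, mu_a = 0.1)
  th <- seq(95, 175, by = 2.5)
  lo <- theory_fsp("azimuthal", geom, p, grid = th)
  hi <- theory_fsp("azimuthal", geom, p, grid = rev(360 - th))
  expect_equal(lo$intensity, rev(hi$intensity), tolerance = 1e-12)
  # unit-area normalization removes any common intensity scale
  cv <- theory_fsp("azimuthal", geom, p)
  cv7 <- cv
  cv7$intensity <- cv$intensity * 7
  n1 <- normalize_curve(cv, window = c(95, 175))
  n7 <- normalize_curve(cv7, window = c(95, 175))
  expect_equal(n1$intensity, n7$intensity)
})

test_that("theory grids are validated", {
  geom <- cylinder_geometry(0.5)
  p <- optical_properties_from_reduced(22, g = 0.9, mu_a = 0.1)
  expect_error(theory_fsp("azimuthal", geom, p, grid = c(80, 100)), "grid")
  expect_error(theory_fsp("longitudinal", geom, p, grid = c(0, 10)), "grid")
  expect_error(theory_fsp("azimuthal", geom, p, grid = numeric(0)), "grid")
})

test_that("azimuthal curve family inverts its order across the window", {
  geom <- cylinder_geometry(0.5)
  fam <- theory_family("azimuthal", 0.5)
  win <- default_ipl_window("azimuthal")
  norm <- lapply(fam, normalize_curve, window = win)
  at <- function(cv, x) approx(cv$abscissa, cv$intensity, x)$y
  # order near the beam center is the reverse of the order at the far edge
  near <- vapply(norm, at, 0, x = 174)
  far <- vapply(norm, at, 0, x = 100)
  expect_true(all(diff(near) > 0) || all(diff(near) < 0))
  expect_true(all(sign(diff(near)) == -sign(diff(far))))
})

test_that("azimuthal FSP converges to the longitudinal one as 1/R0", {
  p <- optical_properties_from_reduced(22, g = 0.9, mu_a = 0.1)
  dev_at <- function(r0) {
    geom <- cylinder_geometry(r0)
    arc <- seq(0.05, 1, by = 0.01)
    th <- 180 - arc / r0 * 180 / pi  # arc length -> azimuth
    az <- theory_fsp("azimuthal", geom, p, grid = rev(th))
    lg <- theory_fsp("longitudinal", geom, p, grid = arc)
    ratio <- rev(az$intensity) / lg$intensity
    max(abs(ratio / ratio[1] - 1))
  }
  devs <- vapply(c(100, 300, 1000), dev_at, 0)
  # curvature correction decays like 1/R0 toward the half-infinite form
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 0.006)
  expect_lt(devs[1], 3.5 * devs[2])
})

test_that("longitudinal theory IPL is radius-invariant, azimuthal is not", {
  radii <- c(0.5, 0.8, 1.0, 2.0)
  lg <- vapply(radii, function(r) {
    estimate_ipl(theory_family("longitudinal", r))$position
  }, 0)
  expect_lt(diff(range(lg)), 0.02)
  az <- vapply(radii, function(r) {
    estimate_ipl(theory_family("azimuthal", r))$position
  }, 0)
  expect_true(all(diff(az) > 0))
})
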