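props16 <- optical_properties_from_reduced(16, g = 0.9)

test_that("step sampling follows the exponential law", {
  expect_equal(sample_step(1, exp(-1)), 1)
  expect_equal(sample_step(10, 0.5), log(2) / 10)
  set.seed(1)
  u <- runif(1e5)
  expect_equal(mean(sample_step(5, u)), 1 / 5, tolerance = 0.01)
  expect_error(sample_step(5, 0), "u")
  expect_error(sample_step(0, 0.5), "mu_t")
})

test_that("Henyey-Greenstein cosine sampling hits endpoints and first moment", {
  expect_equal(sample_hg_cosine(0.9, 1), 1)
  expect_equal(sample_hg_cosine(0.9, 0), -1)
  set.seed(2)
  u <- runif(1e5)
  expect_equal(mean(sample_hg_cosine(0.9, u)), 0.9, tolerance = 0.005 / 0.9)
  expect_true(all(abs(sample_hg_cosine(0.9, u)) <= 1))
  # isotropic limit: uniform cosine
  expect_equal(mean(sample_hg_cosine(0, u)), 0, tolerance = 0.01)
})

test_that("deflection preserves the norm and handles degenerate cosines", {
  d <- c(0, 0, 1)
  expect_equal(deflect(d, 1, 0.3), d)
  expect_equal(deflect(d, -1, 1.2), -d, tolerance = 1e-12)
  set.seed(3)
  v <- c(1, 2, -0.5); v <- v / sqrt(sum(v^2))
  for (i in 1:1e4) {
    v <- deflect(v, runif(1, -1, 1), runif(1, 0, 2 * pi))
  }
  expect_equal(sum(v^2), 1, tolerance = 1e-6)
})

test_that("lumen intersection solves the radial chord and rejects tangents", {
  hit <- intersect_lumen(c(0, 0, 0.6), c(0, 0, -1), 0.2, 0.5)
  expect_equal(hit$distance, 0.1)
  expect_equal(hit$hit_point, c(0, 0, 0.5))
  # heading outward: no hit
  expect_null(intersect_lumen(c(0, 0, 0.6), c(0, 0, 1), 10, 0.5))
  # tangential miss
  expect_null(intersect_lumen(c(0.6, 0, 0), c(0, 0, 1), 10, 0.5))
  expect_error(intersect_lumen(c(0, 0, 0.1), c(0, 0, 1), 1, 0.5), "tissue")
})

test_that("lumen intersection agrees with a segment-marching oracle", {
  set.seed(4)
  rin <- 0.5
  n_checked <- 0
  for (i in 1:600) {
    # random start in the tissue shell, random direction, random step
    r <- runif(1, rin, rin + 0.3)
    ang <- runif(1, 0, 2 * pi)
    p0 <- c(r * cos(ang), runif(1, -1, 1), r * sin(ang))
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    step <- runif(1, 0, 0.8)
    got <- intersect_lumen(p0, dir, step, rin)
    want <- march_intersect(p0, dir, step, rin)
    if (is.null(want)) {
      # marching can only miss grazing hits shorter than its resolution
      if (!is.null(got)) {
        depth <- rin - sqrt(sum((p0 + got$distance * dir)[c(1, 3)]^2))
        expect_lt(abs(depth), 1e-6)
      }
    } else {
      expect_false(is.null(got))
      expect_lt(abs(got$distance - want), 2e-4)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 50)
})

test_that("photon counts are conserved and tallies deterministic per seed", {
  cfg <- mc_config(cylinder_geometry(0.5), props16, n_photons = 2e4,
                   seed = 11)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  tl <- r1$tally
  expect_equal(tl$n_detected + tl$n_lost_outer + tl$n_lost_axial,
               cfg$n_photons)
  expect_identical(r1$tally$azimuthal_hist, r2$tally$azimuthal_hist)
  expect_identical(r1$tally$longitudinal_hist, r2$tally$longitudinal_hist)
  # mu_a = 0: unit weights, so total tallied weight equals n_detected
  expect_equal(sum(tl$azimuthal_hist), tl$n_detected)
  cfg3 <- mc_config(cylinder_geometry(0.5), props16, n_photons = 2e4,
                    seed = 12)
  r3 <- run_simulation(cfg3)
  expect_false(identical(r1$tally$azimuthal_hist, r3$tally$azimuthal_hist))
})

test_that("azimuthal tally is mirror-symmetric about 180 degrees", {
  cfg <- mc_config(cylinder_geometry(0.5), props16, n_photons = 1e5,
                   seed = 21)
  r <- run_simulation(cfg)
  h <- r$tally$azimuthal_hist
  lo <- h[seq_len(length(h) / 2)]
  hi <- rev(h[(length(h) / 2 + 1):length(h)])
  keep <- (lo + hi) >= 25
  z <- (lo[keep] - hi[keep]) / sqrt(lo[keep] + hi[keep])
  expect_true(all(abs(z) < 3 + 1e-9) || mean(abs(z) < 3) > 0.99)
})

test_that("diffusive trapping: huge scattering confines exits to the source", {
  props_big <- optical_properties(0, 1e4, 0)
  cfg <- mc_config(cylinder_geometry(0.5), props_big, n_photons = 2000,
                   seed = 5)
  r <- run_simulation(cfg, keep_records = TRUE)
  expect_gt(r$tally$n_detected / cfg$n_photons, 0.9)
  expect_lt(median(abs(r$records$exit_y)), 0.05)
  expect_lt(median(abs(r$records$exit_azimuth - 180)), 10)
})

test_that("without scattering every photon crosses the thin shell outward", {
  props_clear <- optical_properties(0, 1e-4, 0)
  geom <- cylinder_geometry(0.5, r_outer = 0.6, axial_halfwidth = 5)
  raw <- iplendo:::.mc_run_cpp(500, 9L, geom$r_inner, geom$r_outer,
                               geom$axial_halfwidth, 0, 1e-4, 0,
                               2, 0.02, 0.05, 5, FALSE, 0L)
  expect_equal(raw$n_lost_outer, 500)
  expect_equal(raw$n_detected, 0)
})

test_that("compiled transport matches the pure-R reference statistically", {
  # small, fast geometry so the R loop stays cheap
  props <- optical_properties(0, 40, 0.5)
  geom <- cylinder_geometry(0.5, r_outer = 1.0, axial_halfwidth = 1.0)
  n_r <- 400
  set.seed(31)
  cfg <- mc_config(geom, props, n_photons = n_r, seed = 31)
  states <- vapply(seq_len(n_r), function(i) propagate(cfg)$status, "")
  p_r <- mean(states == "detected")
  cfg2 <- mc_config(geom, props, n_photons = 2e4, seed = 32)
  r <- run_simulation(cfg2)
  p_c <- r$tally$n_detected / cfg2$n_photons
  se <- sqrt(p_r * (1 - p_r) / n_r + p_c * (1 - p_c) / cfg2$n_photons)
  expect_lt(abs(p_r - p_c), 4 * se)
})

test_that("two seeds give consistent normalized azimuthal curves", {
  geom <- cylinder_geometry(0.5)
  mk <- function(seed) {
    cfg <- mc_config(geom, props16, n_photons = 1e5, seed = seed)
    run_simulation(cfg)
  }
  r1 <- mk(41); r2 <- mk(42)
  h1 <- r1$tally$azimuthal_hist; h2 <- r2$tally$azimuthal_hist
  keep <- (h1 + h2) >= 50
  z <- (h1[keep] - h2[keep]) / sqrt(h1[keep] + h2[keep])
  expect_gt(mean(abs(z) < 3), 0.98)
})

test_that("empty tallies raise an explicit error", {
  props_clear <- optical_properties(0, 1e-4, 0)
  geom <- cylinder_geometry(0.5, r_outer = 0.6)
  cfg <- mc_config(geom, props_clear, n_photons = 10, seed = 1)
  expect_error(run_simulation(cfg), "detected")
})
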