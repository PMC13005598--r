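test_that("beam center: single bright pixel and sub-pixel Gaussian spot", {
  m <- matrix(0, 40, 60)
  m[10, 20] <- 1
  # isolated single pixel is removed by the median filter; embed a small
  # bright plateau so the peak survives
  m[9:11, 19:21] <- 1
  fr <- endoscope_frame(m, gsd = 0.01, view = "longitudinal")
  expect_equal(find_beam_center(fr), c(10, 20), tolerance = 1e-8)
  # Gaussian spot at a fractional center
  truth <- c(17.3, 33.7)
  g <- outer(1:40, 1:60, function(r, c2)
    exp(-((r - truth[1])^2 + (c2 - truth[2])^2) / (2 * 2.5^2)))
  fr2 <- endoscope_frame(g, gsd = 0.01, view = "longitudinal")
  expect_equal(find_beam_center(fr2), truth, tolerance = 0.1)
  expect_error(find_beam_center(endoscope_frame(matrix(1, 5, 5), 0.01,
                                                "longitudinal")),
               "constant")
})

test_that("two equal peaks give the midpoint with a warning", {
  m <- matrix(0, 40, 60)
  m[9:11, 9:11] <- 1
  m[9:11, 49:51] <- 1
  fr <- endoscope_frame(m, gsd = 0.01, view = "longitudinal")
  expect_warning(ctr <- find_beam_center(fr), "peak")
  expect_equal(ctr, c(10, 30), tolerance = 1e-8)
})

test_that("longitudinal profile equals a single row for column-constant frames", {
  prof_truth <- 100 * exp(-seq(0, 2, length.out = 81))
  m <- matrix(rep(prof_truth, each = 41), nrow = 41)
  fr <- endoscope_frame(m, gsd = 0.01, view = "longitudinal")
  cv <- longitudinal_profile(fr, center = c(21, 41), band_halfwidth_rows = 5)
  # columns are constant: the band average equals the single center row
  cv1 <- longitudinal_profile(fr, center = c(21, 41), band_halfwidth_rows = 0)
  expect_equal(cv$intensity, cv1$intensity)
  expect_equal(length(cv$abscissa), 41)
  expect_equal(cv$abscissa[2] - cv$abscissa[1], 0.01)
  expect_error(longitudinal_profile(fr, center = c(2, 41),
                                    band_halfwidth_rows = 5), "band")
})

test_that("rendered longitudinal frame round-trips its truth curve", {
  x <- seq(0, 1.2, by = 0.005)
  truth <- fsp_curve(x, 50 * exp(-2.2 * x) + 5, "longitudinal", 1)
  sp <- render_spec(truth, view = "longitudinal", frame_shape = c(101, 221),
                    gsd = 0.005, poisson_scale = 400, gaussian_read_sd = 0.2,
                    seed = 7)
  fr <- render_frame(sp)
  cv <- longitudinal_profile(fr, band_halfwidth_rows = 5)
  want <- approx(truth$abscissa, truth$intensity, cv$abscissa)$y
  scale <- sum(cv$intensity * want) / sum(want^2)
  rms <- sqrt(mean((cv$intensity / scale - want)^2)) / mean(want)
  expect_lt(rms, 0.02)
})

test_that("azimuthal profile: uniform ring is flat for any rotation", {
  x <- seq(0.5, 359.5, by = 1)
  truth <- fsp_curve(x, rep(3, length(x)), "azimuthal", 1)
  sp <- render_spec(truth, view = "azimuthal", frame_shape = c(151, 151),
                    gsd = 0.01, seed = 3)
  fr <- render_frame(sp)
  cv <- azimuthal_profile(fr, center = c(76, 76))
  # pixelated annulus sampling leaves a few percent angular ripple
  expect_lt(diff(range(cv$intensity)) / mean(cv$intensity), 0.05)
})

test_that("azimuthal profile recovers a known angular decay after realignment", {
  x <- seq(0.5, 359.5, by = 1)
  d <- pmin(abs(x - 180), 360 - abs(x - 180))
  truth <- fsp_curve(x, 40 * exp(-d / 60) + 2, "azimuthal", 1)
  sp <- render_spec(truth, view = "azimuthal", frame_shape = c(201, 201),
                    gsd = 0.01, poisson_scale = 800, gaussian_read_sd = 0.05,
                    seed = 11, ring_radius_px = 70, ring_sigma_px = 4)
  fr <- render_frame(sp)
  cv <- azimuthal_profile(fr, center = c(101, 101))
  want <- approx(truth$abscissa, truth$intensity, cv$abscissa)$y
  scale <- sum(cv$intensity * want) / sum(want^2)
  rms <- sqrt(mean((cv$intensity / scale - want)^2)) / mean(want)
  # whole-slice realignment leaves up to half a 3-degree slice of offset
  expect_lt(rms, 0.06)
  # rotating the frame by 90 degrees leaves the realigned profile unchanged
  rot <- endoscope_frame(t(fr$pixels)[, nrow(fr$pixels):1], fr$gsd,
                         "azimuthal")
  cv_rot <- azimuthal_profile(rot, center = c(101, 101))
  expect_equal(cv_rot$intensity, cv$intensity, tolerance = 0.05)
})

test_that("hole center detection finds the dark lumen centroid", {
  m <- matrix(1, 101, 101)
  rr <- row(m) - 45; cc <- col(m) - 55
  m[rr^2 + cc^2 < 20^2] <- 0.01
  fr <- endoscope_frame(m, gsd = 0.01, view = "azimuthal")
  expect_equal(find_hole_center(fr), c(45, 55), tolerance = 0.5)
})

test_that("frames round-trip through TIFF and PNG files", {
  m <- matrix(runif(300), 15, 20)
  fr <- endoscope_frame(m, gsd = 0.02, view = "longitudinal")
  # TIFF is written at 16 bits, PNG at the writer's 8-bit default
  for (spec in list(c("tif", 2 / 65535), c("png", 1 / 255))) {
    path <- tempfile(fileext = paste0(".", spec[1]))
    write_frame(fr, path)
    back <- read_frame(path, gsd = 0.02, view = "longitudinal")
    expect_equal(back$pixels, fr$pixels / max(fr$pixels),
                 tolerance = as.numeric(spec[2]))
    unlink(path)
  }
})
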