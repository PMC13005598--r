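#' Endoscope frame
#'
#' A grayscale intensity frame plus its ground sample distance (physical
#' size of one pixel at the object plane) and viewing direction.
#'
#' @param pixels numeric matrix of nonnegative intensities (rows = image
#'   rows). Color arrays (3d, last dim = channels) are reduced by channel
#'   selection.
#' @param gsd ground sample distance, cm per pixel (> 0).
#' @param view `"longitudinal"` or `"azimuthal"`.
#' @param channel channel picked from color input, default 1 (red; matches
#'   a HeNe 632.8 nm source).
#' @return An object of class `endoscope_frame`.
#' @export
endoscope_frame <- function(pixels, gsd,
                            view = c("longitudinal", "azimuthal"),
                            channel = 1) {
  view <- match.arg(view)
  if (length(dim(pixels)) == 3) pixels <- pixels[, , channel]
  pixels <- as.matrix(pixels)
  if (gsd <= 0) stop("gsd must be > 0")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixels must be finite and nonnegative")
  structure(list(pixels = pixels, gsd = gsd, view = view),
            class = "endoscope_frame")
}

#' Read an endoscope frame from a TIFF or PNG file
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @inheritParams endoscope_frame
#' @return An `endoscope_frame`.
#' @export
read_frame <- function(path, gsd, view = c("longitudinal", "azimuthal"),
                       channel = 1) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext))
  endoscope_frame(img, gsd = gsd, view = view, channel = channel)
}

#' Write an endoscope frame to a 16-bit grayscale image file
#'
#' Intensities are rescaled to `[0, 1]` by the frame maximum.
#'
#' @param frame an [endoscope_frame()].
#' @param path output path (`.tif`, `.tiff` or `.png`).
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "endoscope_frame"))
  img <- frame$pixels / max(frame$pixels, 1e-300)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16),
         png = png::writePNG(img, path),
         stop("unsupported image format: ", ext))
  invisible(path)
}

# 3x3 median filter via shifted stacks (edges keep original values)
.median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(m)
  stack <- array(NA_real_, c(nr - 2, nc - 2, 9))
  k <- 0
  for (dr in 0:2) for (dc in 0:2) {
    k <- k + 1
    stack[, , k] <- m[(1 + dr):(nr - 2 + dr), (1 + dc):(nc - 2 + dc)]
  }
  out <- m
  out[2:(nr - 1), 2:(nc - 1)] <- apply(stack, c(1, 2), stats::median)
  out
}

#' Locate the beam center in a frame
#'
#' Intensity-weighted centroid of the pixels above the 99.5th percentile of
#' a 3x3 median-filtered copy of the frame. Deterministic. If the bright
#' pixels form more than one connected cluster (separated by more than
#' `multi_peak_gap` pixels along either axis) a multi-peak warning is
#' raised and the overall centroid returned.
#'
#' @param frame an [endoscope_frame()].
#' @param quantile brightness quantile defining the peak region.
#' @param multi_peak_gap separation (pixels) that triggers the warning.
#' @return `c(row, col)` in (possibly fractional) pixel coordinates.
#' @export
find_beam_center <- function(frame, quantile = 0.995, multi_peak_gap = 10) {
  stopifnot(inherits(frame, "endoscope_frame"))
  m <- frame$pixels
  if (max(m) == min(m)) stop("constant frame has no beam center")
  mf <- .median3(m)
  thr <- stats::quantile(mf, quantile)
  idx <- which(mf >= thr & mf > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) idx <- which(mf == max(mf), arr.ind = TRUE)
  w <- mf[idx]
  ctr <- c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
  # crude multi-peak check: bright pixels split into distant groups
  if (nrow(idx) > 1) {
    spread_r <- diff(range(idx[, 1])); spread_c <- diff(range(idx[, 2]))
    if (spread_r > multi_peak_gap || spread_c > multi_peak_gap) {
      gaps_r <- diff(sort(unique(idx[, 1]))); gaps_c <- diff(sort(unique(idx[, 2])))
      if (any(gaps_r > multi_peak_gap) || any(gaps_c > multi_peak_gap))
        warning("multiple bright peaks detected; centroid spans them")
    }
  }
  ctr
}

#' Extract the longitudinal intensity profile from a frame
#'
#' Averages a band of rows centered on the beam center and folds the two
#' sides of the beam into a one-sided profile of intensity versus distance
#' (cm, via the gsd) from the center column.
#'
#' @param frame a longitudinal-view [endoscope_frame()].
#' @param center `c(row, col)` beam center; found with
#'   [find_beam_center()] when `NULL`.
#' @param band_halfwidth_rows rows averaged on each side of the center row
#'   (default 5, i.e. an 11-row band).
#' @return An [fsp_curve()] (direction `"longitudinal"`, abscissa cm).
#' @export
longitudinal_profile <- function(frame, center = NULL,
                                 band_halfwidth_rows = 5) {
  stopifnot(inherits(frame, "endoscope_frame"))
  if (frame$view != "longitudinal") stop("frame is not a longitudinal view")
  if (is.null(center)) center <- find_beam_center(frame)
  m <- frame$pixels
  r0 <- round(center[1])
  rows <- (r0 - band_halfwidth_rows):(r0 + band_halfwidth_rows)
  if (min(rows) < 1 || max(rows) > nrow(m))
    stop("row band exceeds the frame")
  prof <- colMeans(m[rows, , drop = FALSE])
  c0 <- center[2]
  # fold the two sides: interpolate each side onto common distances
  max_px <- min(c0 - 1, ncol(m) - c0)
  d_px <- seq(0, floor(max_px), by = 1)
  cols <- seq_len(ncol(m))
  left <- stats::approx(cols, prof, xout = c0 - d_px, rule = 2)$y
  right <- stats::approx(cols, prof, xout = c0 + d_px, rule = 2)$y
  folded <- (left + right) / 2
  fsp_curve(d_px * frame$gsd + 1e-12 * (d_px == 0), pmax(folded, 0),
            direction = "longitudinal", normalization = "raw")
}

#' Locate the lumen (hole) center in an azimuthal frame
#'
#' Centroid of the low-intensity lumen region, taken as the pixels below
#' the given intensity quantile.
#'
#' @param frame an azimuthal-view [endoscope_frame()].
#' @param quantile intensity quantile bounding the dark region (default 0.1).
#' @return `c(row, col)`.
#' @export
find_hole_center <- function(frame, quantile = 0.1) {
  stopifnot(inherits(frame, "endoscope_frame"))
  m <- frame$pixels
  thr <- stats::quantile(m, quantile)
  idx <- which(m <= thr, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no dark lumen region found")
  unname(colMeans(idx[, 1:2, drop = FALSE]))
}

#' Extract the azimuthal intensity profile from a frame
#'
#' Polar resampling about the lumen center: the ring radius is the radius
#' maximizing the angular mean intensity; an annulus of
#' `annulus_halfwidth` pixels is averaged radially and binned into equal
#' angular slices. The slice with maximal intensity is relabelled
#' 180 degrees (the beam center), making the profile invariant to frame
#' rotation.
#'
#' @param frame an azimuthal-view [endoscope_frame()].
#' @param center `c(row, col)` hole center; detected with
#'   [find_hole_center()] when `NULL`.
#' @param slice_deg angular slice width, degrees (default 3).
#' @param annulus_halfwidth annulus half-width, pixels (default 5).
#' @return An [fsp_curve()] (direction `"azimuthal"`, abscissa degrees,
#'   beam center at 180).
#' @export
azimuthal_profile <- function(frame, center = NULL, slice_deg = 3,
                              annulus_halfwidth = 5) {
  stopifnot(inherits(frame, "endoscope_frame"))
  if (frame$view != "azimuthal") stop("frame is not an azimuthal view")
  m <- frame$pixels
  if (is.null(center)) center <- find_hole_center(frame)
  nr <- nrow(m); nc <- ncol(m)
  rr <- row(m) - center[1]; cc <- col(m) - center[2]
  rad <- sqrt(rr^2 + cc^2)
  ang <- (atan2(cc, -rr) * 180 / pi) %% 360  # 0 at top, clockwise-free convention
  max_rad <- floor(min(center[1] - 1, nr - center[1],
                       center[2] - 1, nc - center[2]))
  if (max_rad < 3) stop("hole center too close to the frame edge")
  # radius of maximal angular mean
  rbin <- pmin(pmax(round(rad), 1), max_rad)
  inside <- rad <= max_rad
  rmeans <- tapply(m[inside], rbin[inside], mean)
  if (diff(range(rmeans)) == 0) stop("no ring detected (flat radial mean)")
  ring_r <- as.numeric(names(rmeans))[which.max(rmeans)]
  sel <- abs(rad - ring_r) <= annulus_halfwidth
  if (!any(sel)) stop("empty annulus")
  # equal angular slices
  n_slices <- round(360 / slice_deg)
  slice <- pmin(floor(ang[sel] / (360 / n_slices)), n_slices - 1)
  prof <- tapply(m[sel], factor(slice, levels = 0:(n_slices - 1)), mean)
  prof[is.na(prof)] <- 0
  prof <- as.numeric(prof)
  # realign: maximal slice becomes 180 degrees
  kmax <- which.max(prof)
  k180 <- floor(180 / (360 / n_slices)) + 1
  prof <- prof[((seq_len(n_slices) - 1 + (kmax - k180)) %% n_slices) + 1]
  centers <- (seq_len(n_slices) - 0.5) * (360 / n_slices)
  fsp_curve(centers, pmax(prof, 0), direction = "azimuthal",
            normalization = "raw")
}
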