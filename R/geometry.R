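# Range-map geometry: Gaussian-derivative gradients, groundtruth tilt and
# slant, and range-to-disparity conversion.

ARCMIN_PER_RAD <- 180 * 60 / pi

# 1D convolution of every column (along = "y", the row/upward axis) or every
# row (along = "x") of a matrix; borders where the kernel overflows are NA.
.conv1 <- function(m, kern, along = c("y", "x")) {
  along <- match.arg(along)
  if (along == "y") {
    out <- stats::filter(m, kern, method = "convolution", sides = 2)
    matrix(as.numeric(out), nrow(m), ncol(m))
  } else {
    out <- stats::filter(t(m), kern, method = "convolution", sides = 2)
    t(matrix(as.numeric(out), ncol(m), nrow(m)))
  }
}

# Gaussian kernel (unit sum) and Gaussian-derivative kernel, truncated at
# 3 space constants.  The derivative kernel is normalized so that its first
# moment is exactly -1: convolution then reproduces the slope of an affine
# input exactly, independent of the discretization of sigma.
.gaussKernels <- function(sigmaPx) {
  r <- ceiling(3 * sigmaPx)
  u <- seq(-r, r)
  g <- exp(-u^2 / (2 * sigmaPx^2))
  g <- g / sum(g)
  d <- (-u * g) / sum(u^2 * g)
  list(g = g, d = d, radius = r)
}

#' Gaussian-derivative gradient of a raster
#'
#' Convolves the raster with x- and y- Gaussian derivative operators of
#' space constant `sigma` (the sigma of `exp(-u^2/2 sigma^2)`), equivalent
#' to smoothing with a 2D Gaussian and then taking partial derivatives.
#' Kernels are truncated at 3 sigma and a border margin of that radius is
#' left undefined (NA) rather than padded.  x increases rightward (columns),
#' y increases upward (rows).
#'
#' @param raster numeric matrix (rows = y upward, cols = x rightward).
#' @param sigma space constant in arcmin; must span at least half a pixel.
#' @param geometry a [ViewingGeometry-class] giving the pixel scale.
#' @return list with `dx`, `dy` (derivatives per arcmin of visual angle,
#'   NA in the border margin) and `margin` (pixels).
#' @examples
#' geom <- ViewingGeometry(1, c(32, 32), fixationDistance = 10)
#' ramp <- outer(rep(1, 32), seq_len(32))  # r = x
#' g <- gaussianGradient(ramp, sigma = 2, geom)
#' g$dx[16, 16]  # 1
#' @export
gaussianGradient <- function(raster, sigma, geometry) {
  ps <- pixelScale(geometry)
  sigmaPx <- sigma / ps
  if (!is.finite(sigmaPx) || sigmaPx < 0.5)
    stop("gaussianGradient: sigma must span at least half a pixel (",
         "sigma = ", sigma, " arcmin, pixel scale = ", ps, " arcmin/px)")
  k <- .gaussKernels(sigmaPx)
  # d/dx: derivative along columns, smoothing along rows; per-pixel units,
  # then rescaled to per-arcmin
  dx <- .conv1(.conv1(raster, k$g, "y"), k$d, "x") / ps
  dy <- .conv1(.conv1(raster, k$g, "x"), k$d, "y") / ps
  list(dx = dx, dy = dy, margin = k$radius)
}

#' Groundtruth tilt (and slant) from a range map
#'
#' Tilt is the orientation of the range gradient: the four-quadrant
#' arctangent of the y- and x- Gaussian-derivative gradients of the range
#' map, in degrees mod 360.  A tilt of 90 means range increasing upward in
#' the visual field (a receding ground plane).  Pixels where the gradient
#' magnitude falls below `tol` (fronto-parallel: no tilt direction) or where
#' the kernel overflows the border are marked undefined.
#'
#' @param scene a [RangeScene-class].
#' @param sigmaTilt space constant of the derivative operator, arcmin
#'   (default 3, roughly a quarter-degree support).
#' @param tol gradient-magnitude tolerance, m per arcmin, below which tilt
#'   is undefined.
#' @return A [TiltMap-class] with signed/unsigned tilt, slant, and the
#'   defined mask.
#' @export
tiltFromRange <- function(scene, sigmaTilt = 3, tol = 1e-9) {
  g <- gaussianGradient(rangeMap(scene), sigmaTilt, sceneGeometry(scene))
  mag <- sqrt(g$dx^2 + g$dy^2)
  defined <- is.finite(mag) & (mag >= tol) & validMask(scene)
  tilt <- (atan2(g$dy, g$dx) / DEG) %% 360
  tilt[!defined] <- NA_real_
  # slant: angle between the line of sight and the surface normal under a
  # small-window approximation; gradient per radian of visual angle
  slant <- atan(mag * ARCMIN_PER_RAD / rangeMap(scene)) / DEG
  slant[!is.finite(slant)] <- NA_real_
  TiltMap(tiltSigned = tilt, slant = slant, definedMask = defined)
}

#' Slant from a range map
#'
#' `arctan(|grad r| / r)` with the gradient taken per radian of visual
#' angle: 0 for fronto-parallel surfaces, approaching 90 for grazing ones.
#'
#' @inheritParams tiltFromRange
#' @return slant raster in degrees (NA where undefined).
#' @export
slantFromRange <- function(scene, sigmaTilt = 3) {
  slantMap(tiltFromRange(scene, sigmaTilt, tol = 0))
}

#' Binocular disparity implied by a range map
#'
#' Relative disparity with respect to the fixation distance,
#' `delta = IPD (1/r - 1/r_fix)`, in arcmin.  Positive values are crossed
#' disparities (nearer than fixation).
#'
#' @param scene a [RangeScene-class].
#' @return disparity raster in arcmin (NA where range is invalid).
#' @export
disparityFromRange <- function(scene) {
  geom <- sceneGeometry(scene)
  r <- rangeMap(scene)
  d <- (geom@ipd / 100) * (1 / r - 1 / geom@fixationDistance) * ARCMIN_PER_RAD
  d[!validMask(scene)] <- NA_real_
  d
}
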