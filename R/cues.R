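# Local image cues to tilt: orientation of the luminance and disparity
# gradients, dominant texture orientation from the local amplitude spectrum,
# and the quantizer feeding the lookup tables.

#' Signed orientation of a cue raster's gradient
#'
#' Four-quadrant arctangent of the Gaussian-derivative gradient of a cue
#' raster (a luminance image or a disparity map), in degrees mod 360.
#' Pixels where the gradient magnitude falls below `tol` are undefined.
#'
#' @param raster cue raster.
#' @param geometry a [ViewingGeometry-class].
#' @param sigmaCue space constant, arcmin (default 6).
#' @param tol gradient-magnitude tolerance (raster units per arcmin).
#' @return list with `orientation` (deg in [0, 360), NA undefined) and
#'   `defined`.
#' @export
orientationCue <- function(raster, geometry, sigmaCue = 6, tol = 1e-9) {
  g <- gaussianGradient(raster, sigmaCue, geometry)
  mag <- sqrt(g$dx^2 + g$dy^2)
  defined <- is.finite(mag) & mag >= tol
  ori <- (atan2(g$dy, g$dx) / DEG) %% 360
  ori[!defined] <- NA_real_
  list(orientation = ori, defined = defined)
}

#' Fold a signed orientation map to unsigned
#'
#' The 180-degree modulus of a signed (period 360) map.
#'
#' @param signedMap degrees.
#' @return degrees in [0, 180).
#' @export
toUnsigned <- function(signedMap) signedMap %% 180

#' Disparity from a stereo pair by windowed cross-correlation
#'
#' Per pixel, the horizontal shift maximizing the windowed normalized
#' cross-correlation between the left image and the shifted right image,
#' with a Gaussian window of space constant `sigma` and 3-point quadratic
#' sub-pixel interpolation around the integer peak.  The integer search
#' range is derived from the scene's distance bounds (plus a 2 px margin)
#' or given explicitly.  Pixels failing a left-right consistency check
#' (disagreement above `consistencyTol` px) are flagged half-occluded;
#' pixels whose window has (near) zero variance are undefined.
#'
#' Sign convention: disparity is that of the right-eye image relative to
#' the left; a right image equal to the left shifted rightward by k px
#' yields -k.  Positive disparities are crossed (nearer than fixation),
#' matching [disparityFromRange()].
#'
#' @param left,right co-registered luminance rasters, or a
#'   [RangeScene-class] as `left` with `right` missing.
#' @param geometry a [ViewingGeometry-class] (taken from the scene when one
#'   is given).
#' @param sigma window/operator space constant, arcmin (default 6).
#' @param searchRangePx integer vector `c(min, max)` of candidate shifts in
#'   px; derived from the scene's range extremes when NULL.
#' @param consistencyTol left-right disagreement threshold, px.
#' @return list with `disparity` (arcmin; NA undefined), `disparityPx`,
#'   `defined`, and `halfOccluded`.
#' @export
computeDisparity <- function(left, right = NULL, geometry = NULL, sigma = 6,
                             searchRangePx = NULL, consistencyTol = 1) {
  if (is(left, "RangeScene")) {
    scene <- left
    geometry <- sceneGeometry(scene)
    if (is.null(searchRangePx)) {
      r <- rangeMap(scene)[validMask(scene)]
      dpx <- (sceneGeometry(scene)@ipd / 100) *
        (1 / range(r) - 1 / geometry@fixationDistance) * ARCMIN_PER_RAD /
        pixelScale(geometry)
      searchRangePx <- c(floor(min(dpx)) - 2L, ceiling(max(dpx)) + 2L)
    }
    left <- leftImage(scene); right <- rightImage(scene)
  }
  stopifnot(!is.null(right), !is.null(geometry))
  if (is.null(searchRangePx)) searchRangePx <- c(-8L, 8L)
  # the estimator scans shifts s of the right image; disparity = -s means a
  # candidate shift range [a, b] px needs s in [-b, -a]
  shifts <- seq.int(-searchRangePx[2] - 1L, -searchRangePx[1] + 1L)
  dL <- .nccDisparity(left, right, shifts, sigma / pixelScale(geometry))
  dR <- .nccDisparity(right, left, -rev(shifts), sigma / pixelScale(geometry))
  # consistency: the two scans should agree (dR estimates the opposite shift)
  mismatch <- abs(dL$shift + dR$shift)
  halfOcc <- is.finite(mismatch) & mismatch > consistencyTol
  dpx <- -dL$shift
  defined <- dL$defined
  dpx[!defined] <- NA_real_
  list(disparity = dpx * pixelScale(geometry), disparityPx = dpx,
       defined = defined, halfOccluded = halfOcc | !defined)
}

# core NCC scan: for each integer shift s, correlate a(x) with b(x + s)
# under a Gaussian window; returns the sub-pixel shift maximizing NCC
.nccDisparity <- function(a, b, shifts, sigmaPx, varTol = 1e-10) {
  ny <- nrow(a); nx <- ncol(a)
  k <- .gaussKernels(max(sigmaPx, 0.6))
  smooth <- function(m) .conv1(.conv1(m, k$g, "y"), k$g, "x")
  ma <- smooth(a); va <- smooth(a * a) - ma^2
  ns <- length(shifts)
  ncc <- array(NA_real_, c(ny, nx, ns))
  for (si in seq_len(ns)) {
    s <- shifts[si]
    bs <- matrix(NA_real_, ny, nx)
    src <- seq_len(nx) + s
    ok <- src >= 1 & src <= nx
    bs[, ok] <- b[, src[ok]]
    mb <- smooth(bs); vb <- smooth(bs * bs) - mb^2
    cv <- smooth(a * bs) - ma * mb
    ncc[, , si] <- cv / sqrt(pmax(va, varTol) * pmax(vb, varTol))
  }
  flat <- is.finite(va) & va < varTol
  nccm <- matrix(ncc, ny * nx, ns)
  nccm[!is.finite(nccm)] <- -Inf
  bestI <- max.col(nccm, ties.method = "first")
  bestV <- nccm[cbind(seq_len(ny * nx), bestI)]
  defined <- is.finite(bestV) & !as.vector(flat)
  # 3-point quadratic sub-pixel refinement around the integer peak
  interior <- bestI > 1L & bestI < ns
  idx <- which(interior & defined)
  frac <- numeric(ny * nx)
  cm <- nccm[cbind(idx, bestI[idx] - 1L)]
  c0 <- nccm[cbind(idx, bestI[idx])]
  cp <- nccm[cbind(idx, bestI[idx] + 1L)]
  den <- cm - 2 * c0 + cp
  f <- ifelse(is.finite(den) & abs(den) > 1e-12, 0.5 * (cm - cp) / den, 0)
  # a perfect-correlation peak is an exact integer shift; the parabola
  # through its neighbors would otherwise bias the apex
  f[c0 >= 1 - 1e-9] <- 0
  frac[idx] <- pmax(pmin(f, 0.5), -0.5)
  shift <- shifts[bestI] + frac
  defined <- defined & interior            # peaks at the range edge: reject
  shift[!defined] <- NA_real_
  list(shift = matrix(shift, ny, nx), defined = matrix(defined, ny, nx),
       ncc = matrix(bestV, ny, nx))
}

#' Dominant texture orientation from the local amplitude spectrum
#'
#' Per pixel, a Gaussian-windowed patch is transformed to its amplitude
#' spectrum (DC removed), and the orientation of the major principal axis
#' of the spectrum's second-moment matrix is reported as the cue, in image
#' orientation degrees mod 180.  For a grating whose luminance varies along
#' x the spectral energy lies on the horizontal frequency axis and the cue
#' is 0; rotating the grating rotates the cue.  Patches whose spectrum is
#' nearly isotropic (principal-axis ratio below `isotropyRatio`) are
#' undefined.
#'
#' @param image luminance raster.
#' @param geometry a [ViewingGeometry-class].
#' @param windowSigma Gaussian window space constant, arcmin (default 6),
#'   truncated at 3 sigma; the patch is the enclosing power-of-two square.
#' @param isotropyRatio guard threshold on sqrt(lambda_max/lambda_min).
#' @param step compute the cue every `step` pixels (others undefined); 1
#'   for a dense map.
#' @return list with `orientation` (deg in [0, 180), NA undefined) and
#'   `defined`.
#' @export
textureCue <- function(image, geometry, windowSigma = 6,
                       isotropyRatio = 1.05, step = 1L) {
  ps <- pixelScale(geometry)
  sigPx <- windowSigma / ps
  r <- ceiling(3 * sigPx)
  P <- 2^ceiling(log2(2 * r + 1))
  half <- P %/% 2
  u <- seq(-half, half - 1)
  w2 <- exp(-outer(u^2, u^2, "+") / (2 * sigPx^2))
  # frequency coordinates matching the raster layout (rows = fy, cols = fx)
  f <- c(0:(half - 1), -half:-1)
  FY <- matrix(f, P, P); FX <- matrix(f, P, P, byrow = TRUE)
  ny <- nrow(image); nx <- ncol(image)
  ori <- matrix(NA_real_, ny, nx)
  rows <- seq(half + 1L, ny - half, by = step)
  cols <- seq(half + 1L, nx - half, by = step)
  for (i in rows) {
    pr <- (i - half):(i + half - 1L)
    for (j in cols) {
      patch <- image[pr, (j - half):(j + half - 1L)] * w2
      patch <- patch - mean(patch)
      A <- Mod(stats::fft(patch))
      A[1, 1] <- 0
      tot <- sum(A)
      if (tot <= 0) next
      mxx <- sum(A * FX * FX); myy <- sum(A * FY * FY)
      mxy <- sum(A * FX * FY)
      tr <- mxx + myy
      dd <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
      lmax <- tr / 2 + dd; lmin <- tr / 2 - dd
      if (lmin <= 0 || sqrt(lmax / lmin) < isotropyRatio) next
      ori[i, j] <- (0.5 * atan2(2 * mxy, mxx - myy) / DEG) %% 180
    }
  }
  list(orientation = ori, defined = is.finite(ori))
}

#' Quantize a cue value into equal-width half-open bins
#'
#' `floor(value * nBins / period)`: bin 0 covers `[0, period/nBins)` and so
#' on.  Values outside `[0, period)` are an error.
#'
#' @param value degrees in [0, period); NA passes through as NA.
#' @param nBins number of bins (default 64).
#' @param period 180 for unsigned cues, 360 for the signed disparity cue.
#' @return integer bin indices in `0:(nBins-1)` (NA where value is NA).
#' @examples
#' quantizeCue(179.999, 64, 180)  # 63
#' quantizeCue(2.8125, 64, 180)   # 1 (exact lower edge of bin 1)
#' @export
quantizeCue <- function(value, nBins = 64L, period = 180) {
  ok <- !is.na(value)
  if (any(value[ok] < 0 | value[ok] >= period))
    stop("quantizeCue: values must lie in [0, period)")
  b <- floor(value * nBins / period)
  b[ok] <- pmin(b[ok], nBins - 1L)   # guard float roundup at the top edge
  storage.mode(b) <- "integer"
  b
}

#' Centers of the quantizer's bins
#'
#' @inheritParams quantizeCue
#' @param bins integer bin indices.
#' @return degrees at bin centers.
#' @export
binCenters <- function(bins, nBins = 64L, period = 180) {
  (bins + 0.5) * period / nBins
}

#' Compute all local cue maps for a scene
#'
#' Runs the disparity estimator on the stereo pair, then the orientation
#' cues: luminance-gradient orientation, disparity-gradient orientation,
#' and texture orientation, each with space constant `sigmaCue`.
#'
#' @param scene a [RangeScene-class].
#' @param sigmaCue cue space constant, arcmin (default 6).
#' @param textureStep stride of the texture-cue scan (1 = dense).
#' @param disparity optional precomputed result of [computeDisparity()].
#' @return A [CueMaps-class].
#' @export
computeCueMaps <- function(scene, sigmaCue = 6, textureStep = 1L,
                           disparity = NULL) {
  geom <- sceneGeometry(scene)
  if (is.null(disparity))
    disparity <- computeDisparity(scene, sigma = sigmaCue)
  lum <- orientationCue(leftImage(scene), geom, sigmaCue)
  dmap <- disparity$disparity
  dmapFilled <- dmap
  dmapFilled[!is.finite(dmapFilled)] <- stats::median(dmap, na.rm = TRUE)
  dori <- orientationCue(dmapFilled, geom, sigmaCue)
  dori$defined <- dori$defined & disparity$defined
  dori$orientation[!dori$defined] <- NA_real_
  tex <- textureCue(leftImage(scene), geom, windowSigma = sigmaCue,
                    step = textureStep)
  new("CueMaps", lumSigned = lum$orientation, dispSigned = dori$orientation,
      texUnsigned = tex$orientation, disparity = dmap,
      lumMask = lum$defined, texMask = tex$defined, dispMask = dori$defined,
      halfOcclusion = disparity$halfOccluded, sigmaCue = sigmaCue)
}
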