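# Central data containers.
#
# Raster convention used throughout the package: a raster is a numeric matrix
# whose COLUMN index is the x (horizontal) image coordinate, increasing
# rightward, and whose ROW index is the y (vertical) coordinate, increasing
# UPWARD in the visual field.  TIFF files (top row first) are flipped on
# read/write so that a tilt of 90 deg always means "range increasing upward"
# (a receding ground plane).

#' Viewing geometry of a stereo scene
#'
#' Angular sampling and binocular geometry shared by all rasters of a scene.
#'
#' @slot pixelScale arcmin of visual angle per pixel.
#' @slot ipd inter-pupillary distance in cm (default 6.5, a typical human
#'   value).
#' @slot fixationDistance fixation distance in m; relative disparity is zero
#'   at this distance.
#' @slot imageSize integer (rows, cols) of the co-registered rasters.
#' @export
setClass("ViewingGeometry",
  representation(pixelScale = "numeric", ipd = "numeric",
                 fixationDistance = "numeric", imageSize = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@pixelScale) != 1L || !is.finite(object@pixelScale) ||
        object@pixelScale <= 0)
      msg <- c(msg, "pixelScale must be a single positive number (arcmin/px)")
    if (length(object@ipd) != 1L || !is.finite(object@ipd) || object@ipd <= 0)
      msg <- c(msg, "ipd must be a single positive number (cm)")
    if (length(object@fixationDistance) != 1L ||
        !is.finite(object@fixationDistance) || object@fixationDistance <= 0)
      msg <- c(msg, "fixationDistance must be a single positive number (m)")
    if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
      msg <- c(msg, "imageSize must be two positive integers (rows, cols)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ViewingGeometry
#'
#' @param pixelScale arcmin per pixel.
#' @param imageSize integer vector (rows, cols).
#' @param ipd inter-pupillary distance, cm.
#' @param fixationDistance fixation distance, m.
#' @return A [ViewingGeometry-class] object.
#' @examples
#' ViewingGeometry(pixelScale = 2, imageSize = c(128, 128),
#'                 fixationDistance = 10)
#' @export
ViewingGeometry <- function(pixelScale, imageSize, ipd = 6.5,
                            fixationDistance = 10) {
  new("ViewingGeometry", pixelScale = as.numeric(pixelScale),
      ipd = as.numeric(ipd), fixationDistance = as.numeric(fixationDistance),
      imageSize = as.integer(imageSize))
}

#' Groundtruth tilt and slant maps
#'
#' Per-pixel signed tilt (period 360), unsigned tilt (period 180), and slant,
#' with a mask of pixels where tilt is defined (the range gradient is
#' non-degenerate and kernels do not overflow the border).
#'
#' @slot tiltSigned degrees in [0, 360) per pixel.
#' @slot tiltUnsigned degrees in [0, 180) per pixel; always the 180-modulus
#'   of the signed tilt.
#' @slot slant degrees in [0, 90) per pixel.
#' @slot definedMask logical matrix, TRUE where tilt is defined.
#' @export
setClass("TiltMap",
  representation(tiltSigned = "matrix", tiltUnsigned = "matrix",
                 slant = "matrix", definedMask = "matrix"),
  validity = function(object) {
    msg <- NULL
    dm <- dim(object@tiltSigned)
    for (s in c("tiltUnsigned", "slant", "definedMask"))
      if (!identical(dim(slot(object, s)), dm))
        msg <- c(msg, sprintf("dim(%s) must match dim(tiltSigned)", s))
    ok <- object@definedMask
    if (is.logical(ok) && any(ok)) {
      ts <- object@tiltSigned[ok]; tu <- object@tiltUnsigned[ok]
      if (any(ts < 0 | ts >= 360, na.rm = TRUE))
        msg <- c(msg, "tiltSigned must lie in [0, 360) where defined")
      if (any(tu < 0 | tu >= 180, na.rm = TRUE))
        msg <- c(msg, "tiltUnsigned must lie in [0, 180) where defined")
      if (max(abs(circDiff(ts %% 180, tu, period = 180)), na.rm = TRUE) > 1e-6)
        msg <- c(msg, "tiltUnsigned must equal tiltSigned mod 180")
    }
    if (is.null(msg)) TRUE else msg
  })

TiltMap <- function(tiltSigned, slant, definedMask) {
  ts <- tiltSigned %% 360
  ts[!definedMask] <- NA_real_
  sl <- slant
  sl[!definedMask] <- NA_real_
  new("TiltMap", tiltSigned = ts, tiltUnsigned = ts %% 180, slant = sl,
      definedMask = definedMask)
}

#' A stereo scene with co-registered range data
#'
#' Left/right luminance images and a per-pixel distance (range) map on a
#' common pixel grid, plus the viewing geometry.  Synthetic scenes carry
#' their analytic groundtruth [TiltMap-class] and a half-occlusion mask for
#' the right image.
#'
#' @slot range per-pixel distance, m.
#' @slot leftImage,rightImage linear luminance, arbitrary units.
#' @slot geometry a [ViewingGeometry-class].
#' @slot validMask logical, TRUE where range is measured.
#' @slot groundtruth a [TiltMap-class], or NULL for scenes whose tilt must be
#'   computed from the range map.
#' @slot halfOcclusion logical matrix (TRUE = visible to one eye only), or
#'   NULL when unknown.
#' @export
setClass("RangeScene",
  representation(range = "matrix", leftImage = "matrix",
                 rightImage = "matrix", geometry = "ViewingGeometry",
                 validMask = "matrix", groundtruth = "ANY",
                 halfOcclusion = "ANY", facetLabels = "ANY"),
  validity = function(object) {
    msg <- NULL
    dm <- dim(object@range)
    for (s in c("leftImage", "rightImage", "validMask"))
      if (!identical(dim(slot(object, s)), dm))
        msg <- c(msg, sprintf("dim(%s) must match dim(range)", s))
    if (!identical(as.integer(dm), object@geometry@imageSize))
      msg <- c(msg, "geometry@imageSize must match raster dimensions")
    r <- object@range[object@validMask]
    if (length(r) && any(!is.finite(r) | r <= 0))
      msg <- c(msg, "range must be positive and finite wherever valid")
    if (!is.null(object@groundtruth) && !is(object@groundtruth, "TiltMap"))
      msg <- c(msg, "groundtruth must be NULL or a TiltMap")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a RangeScene
#'
#' @param range distance raster, m (rows = y upward, cols = x rightward).
#' @param leftImage,rightImage luminance rasters.
#' @param geometry a [ViewingGeometry-class].
#' @param validMask logical raster; defaults to finite positive range.
#' @param groundtruth optional [TiltMap-class] with analytic tilt/slant.
#' @param halfOcclusion optional logical raster of half-occluded pixels.
#' @param facetLabels optional integer raster of surface/facet identity
#'   (synthetic scenes).
#' @return A [RangeScene-class].
#' @export
RangeScene <- function(range, leftImage, rightImage, geometry,
                       validMask = NULL, groundtruth = NULL,
                       halfOcclusion = NULL, facetLabels = NULL) {
  if (is.null(validMask)) validMask <- is.finite(range) & range > 0
  new("RangeScene", range = range, leftImage = leftImage,
      rightImage = rightImage, geometry = geometry, validMask = validMask,
      groundtruth = groundtruth, halfOcclusion = halfOcclusion,
      facetLabels = facetLabels)
}

#' Local image cues to surface tilt
#'
#' Signed orientation maps of the luminance and disparity gradients, the
#' unsigned texture orientation, the disparity map they derive from, and
#' per-cue defined masks.  Unsigned cues are the 180-degree modulus of the
#' signed ones.
#'
#' @slot lumSigned,dispSigned degrees in [0, 360) per pixel (NA undefined).
#' @slot texUnsigned degrees in [0, 180) per pixel.
#' @slot disparity disparity in arcmin per pixel (positive = crossed,
#'   nearer than fixation).
#' @slot lumMask,texMask,dispMask per-cue defined masks.
#' @slot halfOcclusion logical, pixels failing the left-right consistency
#'   check of the disparity estimator.
#' @slot sigmaCue space constant of the gradient/window operators, arcmin.
#' @export
setClass("CueMaps",
  representation(lumSigned = "matrix", dispSigned = "matrix",
                 texUnsigned = "matrix", disparity = "matrix",
                 lumMask = "matrix", texMask = "matrix", dispMask = "matrix",
                 halfOcclusion = "matrix", sigmaCue = "numeric"),
  validity = function(object) {
    msg <- NULL
    dm <- dim(object@lumSigned)
    for (s in c("dispSigned", "texUnsigned", "disparity", "lumMask",
                "texMask", "dispMask", "halfOcclusion"))
      if (!identical(dim(slot(object, s)), dm))
        msg <- c(msg, sprintf("dim(%s) must match dim(lumSigned)", s))
    if (is.null(msg)) TRUE else msg
  })

#' Lookup tables of conditional circular means
#'
#' Stage-one estimator state: a 64x64x64 table over quantized unsigned cue
#' triplets (luminance, texture, disparity) accumulating unit phasors of
#' unsigned groundtruth tilt, and a 64-cell table over the quantized signed
#' disparity cue accumulating phasors of signed tilt.  Conditional means are
#' derived from the accumulators, so tables trained on disjoint scene sets
#' merge exactly.
#'
#' @slot nBins bins per cue axis (64).
#' @slot cosU,sinU,countU numeric arrays, dim (nBins, nBins, nBins):
#'   accumulated cos/sin of unsigned tilt (mapped per `method`) and counts.
#' @slot cosS,sinS,countS length-nBins accumulators of signed tilt phasors.
#' @slot method "printed" (phasors at the raw unsigned angle, mean reduced
#'   mod 180) or "doubling" (standard orientation statistics: angles doubled
#'   before summation, mean halved).
#' @slot meta list of provenance (sigma values, training pixel count).
#' @export
setClass("TiltLookup",
  representation(nBins = "integer", cosU = "array", sinU = "array",
                 countU = "array", cosS = "numeric", sinS = "numeric",
                 countS = "numeric", method = "character", meta = "list"),
  validity = function(object) {
    msg <- NULL
    n <- object@nBins
    if (!identical(dim(object@cosU), c(n, n, n)))
      msg <- c(msg, "cosU must have dim (nBins, nBins, nBins)")
    if (!identical(dim(object@sinU), dim(object@cosU)) ||
        !identical(dim(object@countU), dim(object@cosU)))
      msg <- c(msg, "sinU/countU must match dim(cosU)")
    if (length(object@cosS) != n || length(object@sinS) != n ||
        length(object@countS) != n)
      msg <- c(msg, "signed tables must have length nBins")
    if (any(object@countU < 0) || any(object@countS < 0))
      msg <- c(msg, "counts must be nonnegative")
    if (!object@method %in% c("printed", "doubling"))
      msg <- c(msg, "method must be 'printed' or 'doubling'")
    if (is.null(msg)) TRUE else msg
  })

#' Per-tilt adaptive pooling specification
#'
#' One row per target-tilt bin: the relative area (normalized to mean 1),
#' aspect ratio, and major-axis orientation of the elliptical pooling region,
#' plus the average equivalent diameter of the generating scene-statistics
#' fits.  As the average area is scaled up or down, these relative
#' proportions are held fixed.
#'
#' @slot table data.frame with columns bin, tiltCenter (deg), relArea,
#'   aspect (>= 1), orientation (deg in [0, 180), major axis).
#' @slot fittedDbar average equivalent diameter (arcmin) of the ellipses fit
#'   to the scene statistics.
#' @slot orientationRule "orthogonal", "aligned", or "fitted".
#' @export
setClass("PoolingSpec",
  representation(table = "data.frame", fittedDbar = "numeric",
                 orientationRule = "character"),
  validity = function(object) {
    msg <- NULL
    need <- c("bin", "tiltCenter", "relArea", "aspect", "orientation")
    if (!all(need %in% names(object@table)))
      msg <- c(msg, paste("table needs columns:", paste(need, collapse = ", ")))
    else {
      if (any(object@table$relArea <= 0)) msg <- c(msg, "relArea must be > 0")
      if (any(object@table$aspect < 1)) msg <- c(msg, "aspect must be >= 1")
      if (abs(mean(object@table$relArea) - 1) > 1e-6)
        msg <- c(msg, "relArea must be normalized to mean 1")
    }
    if (is.null(msg)) TRUE else msg
  })

## ---- accessors ----

#' @describeIn RangeScene-class the range raster (m).
#' @param x an object.
#' @export
setMethod("rangeMap", "RangeScene", function(x) x@range)

#' @describeIn RangeScene-class left-eye luminance raster.
#' @export
setMethod("leftImage", "RangeScene", function(x) x@leftImage)

#' @describeIn RangeScene-class right-eye luminance raster.
#' @export
setMethod("rightImage", "RangeScene", function(x) x@rightImage)

#' @describeIn RangeScene-class the scene's [ViewingGeometry-class].
#' @export
setMethod("sceneGeometry", "RangeScene", function(x) x@geometry)

#' @describeIn RangeScene-class logical raster of measured-range pixels.
#' @export
setMethod("validMask", "RangeScene", function(x) x@validMask)

#' @describeIn RangeScene-class analytic groundtruth [TiltMap-class] or NULL.
#' @export
setMethod("groundtruth", "RangeScene", function(x) x@groundtruth)

#' @describeIn RangeScene-class half-occlusion mask or NULL.
#' @export
setMethod("halfOcclusionMask", "RangeScene", function(x) x@halfOcclusion)

#' @describeIn ViewingGeometry-class arcmin per pixel.
#' @param x an object.
#' @export
setMethod("pixelScale", "ViewingGeometry", function(x) x@pixelScale)

#' @describeIn TiltMap-class signed tilt raster, deg in [0, 360).
#' @param x an object.
#' @export
setMethod("tiltSigned", "TiltMap", function(x) x@tiltSigned)

#' @describeIn TiltMap-class unsigned tilt raster, deg in [0, 180).
#' @export
setMethod("tiltUnsigned", "TiltMap", function(x) x@tiltUnsigned)

#' @describeIn TiltMap-class slant raster, deg in [0, 90).
#' @export
setMethod("slantMap", "TiltMap", function(x) x@slant)

#' @describeIn TiltMap-class logical raster, TRUE where tilt is defined.
#' @export
setMethod("definedMask", "TiltMap", function(x, ...) x@definedMask)

#' @describeIn CueMaps-class defined mask; `cue` one of "lum", "tex",
#'   "disp", or "all" (the intersection, excluding half-occluded pixels).
#' @param cue cue name.
#' @param ... unused.
#' @export
setMethod("definedMask", "CueMaps", function(x, cue = "all", ...) {
  switch(cue,
         lum = x@lumMask, tex = x@texMask, disp = x@dispMask,
         all = x@lumMask & x@texMask & x@dispMask & !x@halfOcclusion,
         stop("unknown cue: ", cue))
})

#' @describeIn CueMaps-class disparity raster, arcmin.
#' @export
setMethod("disparityMap", "CueMaps", function(x) x@disparity)

#' @describeIn CueMaps-class half-occlusion mask from the left-right
#'   consistency check.
#' @export
setMethod("halfOcclusionMask", "CueMaps", function(x) x@halfOcclusion)

#' @describeIn CueMaps-class a cue raster: "lum_signed", "disp_signed",
#'   "lum_unsigned", "tex_unsigned", or "disp_unsigned".
#' @export
setMethod("cueMap", "CueMaps", function(x, cue) {
  switch(cue,
         lum_signed = x@lumSigned,
         disp_signed = x@dispSigned,
         lum_unsigned = x@lumSigned %% 180,
         tex_unsigned = x@texUnsigned,
         disp_unsigned = x@dispSigned %% 180,
         stop("unknown cue: ", cue))
})

#' @describeIn TiltLookup-class number of bins per cue axis.
#' @param x an object.
#' @export
setMethod("nBins", "TiltLookup", function(x) x@nBins)

#' @describeIn PoolingSpec-class the per-bin table of relative area, aspect
#'   ratio, and orientation.
#' @param x an object.
#' @export
setMethod("poolingTable", "PoolingSpec", function(x) x@table)

#' @describeIn PoolingSpec-class average equivalent diameter (arcmin) of the
#'   scene-statistics fits.
#' @export
setMethod("fittedDiameter", "PoolingSpec", function(x) x@fittedDbar)

## ---- show methods ----

setMethod("show", "ViewingGeometry", function(object) {
  cat(sprintf("ViewingGeometry: %d x %d px, %.3g arcmin/px, IPD %.2f cm, fixation %.2f m\n",
              object@imageSize[1], object@imageSize[2], object@pixelScale,
              object@ipd, object@fixationDistance))
})

setMethod("show", "RangeScene", function(object) {
  r <- object@range[object@validMask]
  cat(sprintf("RangeScene: %d x %d px (%.2f x %.2f deg)\n",
              nrow(object@range), ncol(object@range),
              nrow(object@range) * object@geometry@pixelScale / 60,
              ncol(object@range) * object@geometry@pixelScale / 60))
  if (length(r))
    cat(sprintf("  range: %.2f - %.2f m; %d valid px\n", min(r), max(r),
                length(r)))
  cat(sprintf("  groundtruth tilt: %s; half-occlusion mask: %s\n",
              if (is.null(object@groundtruth)) "absent" else "present",
              if (is.null(object@halfOcclusion)) "absent" else "present"))
})

setMethod("show", "TiltMap", function(object) {
  n <- sum(object@definedMask)
  cat(sprintf("TiltMap: %d x %d px, %d defined (%.1f%%)\n",
              nrow(object@tiltSigned), ncol(object@tiltSigned), n,
              100 * n / length(object@tiltSigned)))
})

setMethod("show", "CueMaps", function(object) {
  cat(sprintf("CueMaps: %d x %d px, sigma_cue %.2g arcmin\n",
              nrow(object@lumSigned), ncol(object@lumSigned), object@sigmaCue))
  for (cue in c("lum", "tex", "disp"))
    cat(sprintf("  %s cue defined: %.1f%%\n", cue,
                100 * mean(definedMask(object, cue))))
  cat(sprintf("  half-occluded: %.2f%%\n", 100 * mean(object@halfOcclusion)))
})

setMethod("show", "TiltLookup", function(object) {
  occ <- sum(object@countU > 0)
  cat(sprintf("TiltLookup: %d^3 unsigned cells (%d occupied, %.2f%%), %d sign cells, method '%s'\n",
              object@nBins, occ, 100 * occ / length(object@countU),
              object@nBins, object@method))
  cat(sprintf("  training samples: unsigned %g, signed %g\n",
              sum(object@countU), sum(object@countS)))
})

setMethod("show", "PoolingSpec", function(object) {
  tb <- object@table
  cat(sprintf("PoolingSpec: %d tilt bins, orientation rule '%s'\n",
              nrow(tb), object@orientationRule))
  cat(sprintf("  fitted average equivalent diameter: %.1f arcmin\n",
              object@fittedDbar))
  cat(sprintf("  relative area %.2f-%.2f, aspect %.2f-%.2f\n",
              min(tb$relArea), max(tb$relArea), min(tb$aspect),
              max(tb$aspect)))
})
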