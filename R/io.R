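# Raster I/O: 32-bit float single-channel TIFFs with a JSON sidecar for the
# viewing geometry.  TIFF files are top-row-first; rasters are flipped on
# read/write so that in memory the row index increases upward.

.flipRows <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

# 32-bit float TIFF storage is defined on [0, 1]; rasters are normalized
# with a per-raster offset/scale recorded in the JSON sidecar
.writeFloatTiff <- function(m, path) {
  m <- .flipRows(m)
  m[!is.finite(m)] <- 0
  off <- min(m); sc <- max(m) - off
  if (sc <= 0) sc <- 1
  tiff::writeTIFF((m - off) / sc, path, bits.per.sample = 32L)
  list(offset = off, scale = sc)
}

.readFloatTiff <- function(path, norm = list(offset = 0, scale = 1)) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  .flipRows(m) * norm$scale + norm$offset
}

# masks are written as plain 8-bit 0/1 rasters, no normalization
.writeMaskTiff <- function(m, path) {
  tiff::writeTIFF(.flipRows(m * 1), path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a RangeScene to a directory
#'
#' Emits `range.tif`, `left.tif`, `right.tif` (32-bit float), `valid.tif`
#' (mask), a `geometry.json` sidecar with
#' `{pixel_scale_arcmin, ipd_cm, fixation_distance_m}`, and, when present,
#' the groundtruth tilt/slant rasters and half-occlusion mask.
#'
#' @param scene a [RangeScene-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRangeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- sceneGeometry(scene)
  norms <- list(
    range = .writeFloatTiff(rangeMap(scene), file.path(dir, "range.tif")),
    left = .writeFloatTiff(leftImage(scene), file.path(dir, "left.tif")),
    right = .writeFloatTiff(rightImage(scene), file.path(dir, "right.tif")))
  .writeMaskTiff(validMask(scene), file.path(dir, "valid.tif"))
  gt <- groundtruth(scene)
  if (!is.null(gt)) {
    ts <- tiltSigned(gt); ts[!definedMask(gt)] <- -1
    sl <- slantMap(gt); sl[!definedMask(gt)] <- -1
    norms$tilt <- .writeFloatTiff(ts, file.path(dir, "tilt.tif"))
    norms$slant <- .writeFloatTiff(sl, file.path(dir, "slant.tif"))
  }
  if (!is.null(halfOcclusionMask(scene)))
    .writeMaskTiff(halfOcclusionMask(scene),
                   file.path(dir, "half_occlusion.tif"))
  jsonlite::write_json(
    list(pixel_scale_arcmin = geom@pixelScale, ipd_cm = geom@ipd,
         fixation_distance_m = geom@fixationDistance, rasters = norms),
    file.path(dir, "geometry.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a RangeScene from a directory written by [writeRangeScene()]
#'
#' @param dir directory containing the raster set and `geometry.json`.
#' @return A [RangeScene-class].
#' @export
readRangeScene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "geometry.json"),
                              simplifyVector = TRUE)
  rng <- .readFloatTiff(file.path(dir, "range.tif"), meta$rasters$range)
  geom <- ViewingGeometry(meta$pixel_scale_arcmin, dim(rng),
                          ipd = meta$ipd_cm,
                          fixationDistance = meta$fixation_distance_m)
  valid <- .readFloatTiff(file.path(dir, "valid.tif")) > 0.5
  gt <- NULL
  if (file.exists(file.path(dir, "tilt.tif"))) {
    ts <- .readFloatTiff(file.path(dir, "tilt.tif"), meta$rasters$tilt)
    sl <- .readFloatTiff(file.path(dir, "slant.tif"), meta$rasters$slant)
    def <- ts >= 0
    ts[!def] <- NA_real_; sl[!def] <- NA_real_
    ts <- pmin(pmax(ts, 0), 360 - 1e-9) %% 360
    gt <- TiltMap(tiltSigned = ts, slant = sl, definedMask = def)
  }
  ho <- NULL
  if (file.exists(file.path(dir, "half_occlusion.tif")))
    ho <- .readFloatTiff(file.path(dir, "half_occlusion.tif")) > 0.5
  rng[!valid] <- NA_real_
  RangeScene(range = rng,
             leftImage = .readFloatTiff(file.path(dir, "left.tif"),
                                        meta$rasters$left),
             rightImage = .readFloatTiff(file.path(dir, "right.tif"),
                                         meta$rasters$right),
             geometry = geom, validMask = valid, groundtruth = gt,
             halfOcclusion = ho)
}

#' Serialize lookup tables to JSON
#'
#' Writes the phasor accumulators, counts, bin count, method, and metadata
#' of a [TiltLookup-class] to a single JSON file (plain text, exactly
#' reconstructable since accumulators are written at full precision).
#'
#' @param lut a [TiltLookup-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLookup <- function(lut, path) {
  obj <- list(nBins = lut@nBins, method = lut@method,
              cosU = as.numeric(lut@cosU), sinU = as.numeric(lut@sinU),
              countU = as.numeric(lut@countU),
              cosS = lut@cosS, sinS = lut@sinS, countS = lut@countS,
              meta = lut@meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read lookup tables written by [writeLookup()]
#'
#' @param path JSON file.
#' @return A [TiltLookup-class].
#' @export
readLookup <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(obj$nBins)
  new("TiltLookup", nBins = n,
      cosU = array(as.numeric(obj$cosU), c(n, n, n)),
      sinU = array(as.numeric(obj$sinU), c(n, n, n)),
      countU = array(as.numeric(obj$countU), c(n, n, n)),
      cosS = as.numeric(obj$cosS), sinS = as.numeric(obj$sinS),
      countS = as.numeric(obj$countS),
      method = obj$method, meta = as.list(obj$meta))
}
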