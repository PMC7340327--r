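# Experimental stimulus sampling: constraint filters on candidate patch
# centres and tilt-balanced selection.

#' Patch selection constraints
#'
#' Acceptance intervals for candidate stimulus patches, all closed on both
#' ends: centre-pixel slant and distance, aperture RMS contrast, and
#' exclusion of half-occluded centres.  Defaults follow the wider-slant
#' condition (slants 30-75 deg); `slantRange = c(30, 60)` gives the
#' narrower one.
#'
#' @param slantRange degrees.
#' @param distanceRange m.
#' @param contrastRange percent RMS.
#' @param excludeHalfOccluded logical.
#' @param apertureDiameter degrees of visual angle (default 3).
#' @return classed list `PatchConstraints`.
#' @export
patchConstraints <- function(slantRange = c(30, 75),
                             distanceRange = c(5, 50),
                             contrastRange = c(5, 40),
                             excludeHalfOccluded = TRUE,
                             apertureDiameter = 3) {
  stopifnot(diff(slantRange) >= 0, diff(distanceRange) >= 0,
            diff(contrastRange) >= 0, apertureDiameter > 0)
  structure(list(slantRange = slantRange, distanceRange = distanceRange,
                 contrastRange = contrastRange,
                 excludeHalfOccluded = excludeHalfOccluded,
                 apertureDiameter = apertureDiameter),
            class = "PatchConstraints")
}

#' RMS contrast of a patch
#'
#' `100 * sd / mean` of the luminance within the aperture, with the
#' standard deviation taken with denominator n (so a patch half 0 and half
#' 2 has contrast exactly 100).
#'
#' @param patch luminance values (vector or matrix).
#' @param mask optional logical aperture mask (same shape).
#' @return percent.
#' @export
rmsContrast <- function(patch, mask = NULL) {
  v <- if (is.null(mask)) as.numeric(patch) else patch[mask]
  v <- v[is.finite(v)]
  if (!length(v)) stop("rmsContrast: empty patch")
  m <- mean(v)
  if (m <= 0) stop("rmsContrast: non-positive mean luminance")
  100 * sqrt(mean((v - m)^2)) / m
}

.apertureMask <- function(radiusPx) {
  R <- max(1L, floor(radiusPx))
  g <- expand.grid(dy = -R:R, dx = -R:R)
  keep <- g$dy^2 + g$dx^2 <= radiusPx^2
  cbind(dy = g$dy[keep], dx = g$dx[keep])
}

#' Filter candidate patches by the sampling constraints
#'
#' Keeps exactly those candidates whose centre-pixel slant, distance, and
#' half-occlusion status and whose aperture RMS contrast satisfy every
#' acceptance interval.  Candidates whose centre tilt or any required
#' quantity is undefined, or whose aperture overflows the image, are
#' dropped.
#'
#' @param candidates data.frame with `scene` (index into `scenes`), `row`,
#'   `col`.
#' @param constraints a [patchConstraints()].
#' @param scenes list of [RangeScene-class] objects whose `groundtruth`
#'   slots hold the tilt/slant maps (computed with [tiltFromRange()] when
#'   absent).
#' @return data.frame of survivors with added columns `tilt`, `slant`,
#'   `distance`, `contrast`, `halfOccluded`, `bin` (24-bin centre-tilt
#'   index).
#' @export
filterPatches <- function(candidates, constraints, scenes) {
  stopifnot(inherits(constraints, "PatchConstraints"))
  if (nrow(candidates) == 0L) return(cbind(candidates, tilt = numeric(0)))
  out <- vector("list", length(scenes))
  for (si in unique(candidates$scene)) {
    sc <- scenes[[si]]
    gt <- groundtruth(sc)
    if (is.null(gt)) gt <- tiltFromRange(sc)
    geom <- sceneGeometry(sc)
    radiusPx <- (constraints$apertureDiameter / 2) * 60 / pixelScale(geom)
    ap <- .apertureMask(radiusPx)
    cc <- candidates[candidates$scene == si, , drop = FALSE]
    ho <- halfOcclusionMask(sc)
    L <- leftImage(sc)
    ny <- nrow(L); nx <- ncol(L)
    res <- lapply(seq_len(nrow(cc)), function(k) {
      r <- cc$row[k]; c <- cc$col[k]
      rr <- r + ap[, "dy"]; cols <- c + ap[, "dx"]
      if (any(rr < 1 | rr > ny | cols < 1 | cols > nx)) return(NULL)
      if (!definedMask(gt)[r, c]) return(NULL)
      data.frame(scene = si, row = r, col = c,
                 tilt = tiltSigned(gt)[r, c], slant = slantMap(gt)[r, c],
                 distance = rangeMap(sc)[r, c],
                 contrast = rmsContrast(L[cbind(rr, cols)]),
                 halfOccluded = if (is.null(ho)) FALSE else ho[r, c])
    })
    out[[si]] <- do.call(rbind, res)
  }
  d <- do.call(rbind, out)
  if (is.null(d) || nrow(d) == 0L) return(candidates[0, , drop = FALSE])
  keep <- d$slant >= constraints$slantRange[1] &
    d$slant <= constraints$slantRange[2] &
    d$distance >= constraints$distanceRange[1] &
    d$distance <= constraints$distanceRange[2] &
    d$contrast >= constraints$contrastRange[1] &
    d$contrast <= constraints$contrastRange[2]
  if (constraints$excludeHalfOccluded) keep <- keep & !d$halfOccluded
  d <- d[keep, , drop = FALSE]
  d$bin <- tiltBin(d$tilt)
  rownames(d) <- NULL
  d
}

#' Tilt-balanced sampling of surviving patches
#'
#' Uniform random selection without replacement of `perBin` patches from
#' each of `nBins` centre-tilt bins, so the output tilt histogram is
#' exactly flat.  An undersupplied bin is an error naming the bin and its
#' deficit.
#'
#' @param survivors data.frame from [filterPatches()] (needs a `bin`
#'   column, or `tilt` from which bins are computed).
#' @param nBins number of tilt bins (default 24).
#' @param perBin patches per bin (default 150).
#' @param seed integer seed; the same seed gives an identical selection.
#' @return data.frame of `nBins * perBin` sampled patches.
#' @export
balancedSample <- function(survivors, nBins = 24L, perBin = 150L,
                           seed = 1L) {
  if (is.null(survivors$bin)) survivors$bin <- tiltBin(survivors$tilt, nBins)
  set.seed(as.integer(seed))
  parts <- vector("list", nBins)
  for (b in 0:(nBins - 1L)) {
    rows <- which(survivors$bin == b)
    if (length(rows) < perBin)
      stop("balancedSample: bin ", b, " has only ", length(rows),
           " survivors (deficit ", perBin - length(rows), ")")
    pick <- if (length(rows) == perBin) rows else
      rows[sample.int(length(rows), perBin)]
    parts[[b + 1L]] <- survivors[pick, , drop = FALSE]
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
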