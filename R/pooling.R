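# Stage 2: global tilt estimates by weighted circular pooling of local
# estimates over fixed circular or adaptive elliptical neighborhoods.

.mkRegion <- function(dxPx, dyPx, weights, shape) {
  keep <- weights > 0
  structure(list(dx = as.integer(dxPx[keep]), dy = as.integer(dyPx[keep]),
                 weights = weights[keep] / sum(weights[keep]), shape = shape),
            class = "PoolingRegion")
}

#' Fixed circular pooling region
#'
#' All pixel offsets within `diameter/2` of the target, equally weighted.
#' Diameters smaller than one pixel give the single-pixel region (under
#' which the global model degenerates exactly to the local model).
#'
#' @param diameter arcmin.
#' @param geometry a [ViewingGeometry-class].
#' @param taper "uniform" (equal weights; the default) or "gaussian"
#'   (weights proportional to a Gaussian with the region's radius as its
#'   2-sigma point).
#' @return A `PoolingRegion`: offsets (`dx`, `dy`, px), normalized
#'   `weights`, and `shape` metadata.
#' @export
circularRegion <- function(diameter, geometry,
                           taper = c("uniform", "gaussian")) {
  taper <- match.arg(taper)
  stopifnot(diameter >= 0)
  ps <- pixelScale(geometry)
  radPx <- (diameter / 2) / ps
  R <- floor(radPx)
  if (R < 1L)
    return(.mkRegion(0L, 0L, 1, list(type = "circle", diameter = diameter)))
  g <- expand.grid(dx = -R:R, dy = -R:R)
  r2 <- (g$dx^2 + g$dy^2) / radPx^2
  inR <- r2 <= 1
  w <- if (taper == "gaussian") exp(-r2[inR] * 2) else rep(1, sum(inR))
  .mkRegion(g$dx[inR], g$dy[inR], w,
            list(type = "circle", diameter = diameter, taper = taper))
}

#' Adaptive elliptical pooling region for a target tilt
#'
#' The ellipse for the target tilt's bin: area `relArea * pi (dBar/2)^2`
#' (so the average area across bins corresponds to the average equivalent
#' diameter `dBar`), with the bin's aspect ratio and major-axis
#' orientation; equal weights inside.  Membership is a center-in-ellipse
#' test.
#'
#' @param targetTilt degrees in [0, 360).
#' @param dBar average equivalent diameter across bins, arcmin.
#' @param spec a [PoolingSpec-class].
#' @param geometry a [ViewingGeometry-class].
#' @param taper as in [circularRegion()].
#' @return A `PoolingRegion`.
#' @export
ellipticalRegion <- function(targetTilt, dBar, spec, geometry,
                             taper = c("uniform", "gaussian")) {
  taper <- match.arg(taper)
  stopifnot(is(spec, "PoolingSpec"), dBar >= 0)
  tab <- poolingTable(spec)
  b <- tiltBin(targetTilt, nrow(tab))
  row <- tab[tab$bin == b, ]
  if (nrow(row) != 1L)
    stop("ellipticalRegion: spec does not cover tilt bin ", b)
  ps <- pixelScale(geometry)
  area <- row$relArea * pi * (dBar / 2)^2          # arcmin^2
  a <- sqrt(area * row$aspect / pi)                 # semi-major, arcmin
  bm <- sqrt(area / (row$aspect * pi))              # semi-minor
  if (a / ps < 1)
    return(.mkRegion(0L, 0L, 1,
                     list(type = "ellipse", bin = b, dBar = dBar)))
  R <- ceiling(a / ps)
  g <- expand.grid(dx = -R:R, dy = -R:R)
  cph <- cos(row$orientation * DEG); sph <- sin(row$orientation * DEG)
  u <- (cph * g$dx + sph * g$dy) * ps
  v <- (-sph * g$dx + cph * g$dy) * ps
  q <- (u / a)^2 + (v / bm)^2
  inR <- q <= 1
  inR[g$dx == 0 & g$dy == 0] <- TRUE                # target always included
  w <- if (taper == "gaussian") exp(-q[inR] * 2) else rep(1, sum(inR))
  .mkRegion(g$dx[inR], g$dy[inR], w,
            list(type = "ellipse", bin = b, dBar = dBar, area = area,
                 aspect = row$aspect, orientation = row$orientation,
                 taper = taper))
}

#' Pool local estimates over a region at one target pixel
#'
#' The weighted circular mean (period 360) of the defined local estimates
#' covered by the region centred on the target; undefined pixels are
#' dropped and weights renormalized.  With no defined estimate the result
#' is undefined (NA); with a degenerate resultant the target's own local
#' estimate is returned and flagged.
#'
#' @param localMap matrix of local signed tilt estimates (deg, NA
#'   undefined).
#' @param region a `PoolingRegion`.
#' @param target `c(row, col)` of the target pixel.
#' @return list with `estimate` (deg in [0, 360) or NA), `nUsed`, and
#'   `fallback` (TRUE when the degenerate-resultant fallback fired).
#' @export
poolEstimates <- function(localMap, region, target) {
  ny <- nrow(localMap); nx <- ncol(localMap)
  r <- target[1] + region$dy; c <- target[2] + region$dx
  inb <- r >= 1 & r <= ny & c >= 1 & c <= nx
  v <- localMap[cbind(r[inb], c[inb])]
  w <- region$weights[inb]
  def <- !is.na(v)
  v <- v[def]; w <- w[def]
  if (!length(v)) return(list(estimate = NA_real_, nUsed = 0L,
                              fallback = FALSE))
  if (length(v) == 1L)
    return(list(estimate = v, nUsed = 1L, fallback = FALSE))
  m <- tryCatch(circMean(v, w, period = 360),
                error = function(e) NULL)
  if (is.null(m))
    return(list(estimate = localMap[target[1], target[2]],
                nUsed = length(v), fallback = TRUE))
  list(estimate = m$mean, nUsed = length(v), fallback = FALSE)
}

#' Global tilt estimates at target pixels
#'
#' Pools a map of local estimates at each target: in "fixed" mode within
#' one circular region of the configured diameter; in "adaptive" mode
#' within the elliptical region keyed either by the groundtruth tilt at
#' the target (oracle analysis) or by the local estimate at the target
#' (single pass, no iteration).
#'
#' @param localMap matrix of local signed tilt estimates (deg, NA
#'   undefined).
#' @param geometry a [ViewingGeometry-class].
#' @param targets n x 2 matrix (row, col); defaults to every defined pixel.
#' @param mode "fixed" or "adaptive".
#' @param diameter pooling diameter (fixed) or average equivalent diameter
#'   dBar (adaptive), arcmin.
#' @param spec a [PoolingSpec-class] (adaptive mode).
#' @param keyMode "groundtruth" or "local_estimate" (adaptive mode).
#' @param keyMap matrix of groundtruth tilts, required when `keyMode =
#'   "groundtruth"`.
#' @param taper as in [circularRegion()].
#' @return vector of global estimates (deg in [0, 360), NA undefined), one
#'   per target row.
#' @export
estimateGlobal <- function(localMap, geometry, targets = NULL,
                           mode = c("fixed", "adaptive"), diameter = 60,
                           spec = NULL, keyMode = c("groundtruth",
                                                    "local_estimate"),
                           keyMap = NULL, taper = "uniform") {
  mode <- match.arg(mode)
  keyMode <- match.arg(keyMode)
  if (is.null(targets)) {
    idx <- which(!is.na(localMap), arr.ind = TRUE)
    targets <- idx
  }
  if (mode == "fixed") {
    region <- circularRegion(diameter, geometry, taper)
    out <- numeric(nrow(targets))
    for (i in seq_len(nrow(targets)))
      out[i] <- poolEstimates(localMap, region, targets[i, ])$estimate
    return(out)
  }
  stopifnot(is(spec, "PoolingSpec"))
  keys <- if (keyMode == "groundtruth") {
    stopifnot(!is.null(keyMap))
    keyMap[targets]
  } else localMap[targets]
  nb <- nrow(poolingTable(spec))
  regions <- vector("list", nb)
  out <- rep(NA_real_, nrow(targets))
  kb <- tiltBin(keys, nb)
  for (i in seq_len(nrow(targets))) {
    if (is.na(kb[i])) next
    b <- kb[i] + 1L
    if (is.null(regions[[b]]))
      regions[[b]] <- ellipticalRegion(tiltBinCenter(kb[i], nb), diameter,
                                       spec, geometry, taper)
    out[i] <- poolEstimates(localMap, regions[[b]], targets[i, ])$estimate
  }
  out
}
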