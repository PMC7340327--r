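# Spatial tilt statistics: the tilt prior, mean absolute tilt-difference
# maps as a function of spatial offset (optionally conditioned on the
# target tilt), and the 2D-Gaussian ellipse fits that parameterize
# adaptive pooling.

#' Target-tilt bin index
#'
#' 24 bins of 15 degrees centred on 0, 15, ..., 345 (so the cardinal tilts
#' sit at bin centres): bin `b` covers `[15b - 7.5, 15b + 7.5)`.
#'
#' @param tilt degrees.
#' @param nBins number of bins over 360 degrees (default 24).
#' @return integer bin indices in `0:(nBins-1)`.
#' @export
tiltBin <- function(tilt, nBins = 24L) {
  w <- 360 / nBins
  as.integer(floor(((tilt + w / 2) %% 360) / w))
}

#' Tilt bin centres
#' @inheritParams tiltBin
#' @param bins integer bin indices.
#' @return degrees.
#' @export
tiltBinCenter <- function(bins, nBins = 24L) (bins * 360 / nBins) %% 360

#' Prior histogram of groundtruth tilt
#'
#' @param tiltMaps a [TiltMap-class] or list of them.
#' @param nBins number of bins (default 24).
#' @return data.frame with `bin`, `center` (deg), `count`, and `p`
#'   (normalized to sum 1).
#' @export
tiltPriorHistogram <- function(tiltMaps, nBins = 24L) {
  if (is(tiltMaps, "TiltMap")) tiltMaps <- list(tiltMaps)
  counts <- numeric(nBins)
  for (tm in tiltMaps) {
    t <- tiltSigned(tm)[definedMask(tm)]
    if (length(t))
      counts <- counts + tabulate(tiltBin(t, nBins) + 1L, nBins)
  }
  if (sum(counts) == 0) stop("tiltPriorHistogram: no defined tilt values")
  data.frame(bin = 0:(nBins - 1), center = tiltBinCenter(0:(nBins - 1), nBins),
             count = counts, p = counts / sum(counts))
}

#' Mean absolute tilt difference as a function of spatial offset
#'
#' For every offset `(dx, dy)` on a pixel grid out to `maxOffset`, the mean
#' absolute circular distance between the tilt at a target pixel and the
#' tilt at the offset neighbor, aggregated over all valid pixel pairs in
#' all scenes — optionally restricted to targets whose tilt falls in one
#' conditioning bin.  Aggregation follows [meanAbsDiff()] (`method
#' = "phasor"` takes the argument of the summed unit phasors of the
#' absolute differences; `"arithmetic"` is the plain mean).
#'
#' @param tiltMaps a [TiltMap-class] or list of them.
#' @param geometry a [ViewingGeometry-class] (for the arcmin offset grid).
#' @param maxOffset largest offset, arcmin.
#' @param condition NULL (all targets) or a target-tilt bin in
#'   `0:(nBins-1)`.
#' @param nBins conditioning bins over 360 deg (default 24).
#' @param step offset-grid step in pixels.
#' @param method "phasor" or "arithmetic".
#' @return A `TiltDiffMap`: list with `dx`, `dy` (arcmin), `meanAbsDiff`
#'   (degrees; rows indexed by dy, cols by dx; NA where no pairs),
#'   `nPairs`, `condition`, `method`.
#' @export
meanDiffMap <- function(tiltMaps, geometry, maxOffset = 60, condition = NULL,
                        nBins = 24L, step = 1L,
                        method = c("phasor", "arithmetic")) {
  method <- match.arg(method)
  if (is(tiltMaps, "TiltMap")) tiltMaps <- list(tiltMaps)
  ps <- pixelScale(geometry)
  R <- max(1L, round(maxOffset / ps))
  offs <- seq(-R, R, by = step)
  no <- length(offs)
  Csum <- matrix(0, no, no); Ssum <- matrix(0, no, no)
  Dsum <- matrix(0, no, no); Np <- matrix(0, no, no)
  for (tm in tiltMaps) {
    A <- tiltSigned(tm)
    def <- definedMask(tm)
    ny <- nrow(A); nx <- ncol(A)
    condMask <- def
    if (!is.null(condition)) {
      b <- matrix(NA_integer_, ny, nx)
      b[def] <- tiltBin(A[def], nBins)
      condMask <- def & !is.na(b) & b == condition
    }
    for (iy in seq_len(no)) {
      dyp <- offs[iy]
      rt <- max(1L, 1L - dyp):min(ny, ny - dyp)
      if (!length(rt)) next
      for (ix in seq_len(no)) {
        dxp <- offs[ix]
        ct <- max(1L, 1L - dxp):min(nx, nx - dxp)
        if (!length(ct)) next
        t0 <- A[rt, ct, drop = FALSE]
        ti <- A[rt + dyp, ct + dxp, drop = FALSE]
        ok <- condMask[rt, ct, drop = FALSE] &
          def[rt + dyp, ct + dxp, drop = FALSE]
        if (!any(ok)) next
        d <- abs((t0[ok] - ti[ok] + 180) %% 360 - 180)
        Csum[iy, ix] <- Csum[iy, ix] + sum(cos(d * DEG))
        Ssum[iy, ix] <- Ssum[iy, ix] + sum(sin(d * DEG))
        Dsum[iy, ix] <- Dsum[iy, ix] + sum(d)
        Np[iy, ix] <- Np[iy, ix] + length(d)
      }
    }
  }
  md <- if (method == "arithmetic") Dsum / Np else
    .meanFromSums(Csum, Ssum, Np)
  md[Np == 0] <- NA_real_
  structure(list(dx = offs * ps, dy = offs * ps, meanAbsDiff = md,
                 nPairs = Np, condition = condition, method = method),
            class = "TiltDiffMap")
}

#' Tilt-conditioned difference maps for every target-tilt bin in one pass
#'
#' Computes the [meanDiffMap()] statistic simultaneously for all `nBins`
#' conditioning bins (one scan of the offset grid, with per-offset
#' aggregation grouped by the target's tilt bin).
#'
#' @inheritParams meanDiffMap
#' @return list of `nBins` `TiltDiffMap`s, one per conditioning bin (bin
#'   order 0, 1, ...).
#' @export
meanDiffMapByTilt <- function(tiltMaps, geometry, maxOffset = 60,
                              nBins = 24L, step = 1L,
                              method = c("phasor", "arithmetic")) {
  method <- match.arg(method)
  if (is(tiltMaps, "TiltMap")) tiltMaps <- list(tiltMaps)
  ps <- pixelScale(geometry)
  R <- max(1L, round(maxOffset / ps))
  offs <- seq(-R, R, by = step)
  no <- length(offs)
  Csum <- array(0, c(nBins, no, no)); Ssum <- array(0, c(nBins, no, no))
  Dsum <- array(0, c(nBins, no, no)); Np <- array(0, c(nBins, no, no))
  for (tm in tiltMaps) {
    A <- tiltSigned(tm)
    def <- definedMask(tm)
    ny <- nrow(A); nx <- ncol(A)
    B <- matrix(NA_integer_, ny, nx)
    B[def] <- tiltBin(A[def], nBins)
    for (iy in seq_len(no)) {
      dyp <- offs[iy]
      rt <- max(1L, 1L - dyp):min(ny, ny - dyp)
      for (ix in seq_len(no)) {
        dxp <- offs[ix]
        ct <- max(1L, 1L - dxp):min(nx, nx - dxp)
        t0 <- A[rt, ct, drop = FALSE]
        ti <- A[rt + dyp, ct + dxp, drop = FALSE]
        b0 <- B[rt, ct, drop = FALSE]
        ok <- !is.na(b0) & def[rt + dyp, ct + dxp, drop = FALSE]
        if (!any(ok)) next
        d <- abs((t0[ok] - ti[ok] + 180) %% 360 - 180)
        acc <- rowsum(cbind(cos(d * DEG), sin(d * DEG), d, 1),
                      group = b0[ok])
        gi <- as.integer(rownames(acc)) + 1L
        Csum[gi, iy, ix] <- Csum[gi, iy, ix] + acc[, 1]
        Ssum[gi, iy, ix] <- Ssum[gi, iy, ix] + acc[, 2]
        Dsum[gi, iy, ix] <- Dsum[gi, iy, ix] + acc[, 3]
        Np[gi, iy, ix] <- Np[gi, iy, ix] + acc[, 4]
      }
    }
  }
  lapply(seq_len(nBins), function(b) {
    md <- if (method == "arithmetic") Dsum[b, , ] / Np[b, , ] else
      .meanFromSums(Csum[b, , ], Ssum[b, , ], Np[b, , ])
    md[Np[b, , ] == 0] <- NA_real_
    structure(list(dx = offs * ps, dy = offs * ps, meanAbsDiff = md,
                   nPairs = Np[b, , ], condition = b - 1L, method = method),
              class = "TiltDiffMap")
  })
}

#' Fit a 2D Gaussian pooling ellipse to a tilt-difference map
#'
#' The difference map is minimal at the centre, so the inverted similarity
#' surface `s = max(diff) - diff` is normalized to unit volume and fit by a
#' zero-centred bivariate Gaussian `a exp(-0.5 o' Sigma^-1 o)` (least
#' squares, with the precision matrix Cholesky-parameterized so the fit is
#' positive definite by construction; moment-matched initialization).  The
#' Gaussian's iso-level curves then match the iso-difference contours; the
#' inversion is recorded in the result.
#'
#' @param diffMap a `TiltDiffMap` from [meanDiffMap()].
#' @return list (class `EllipseFit`) with `covariance` (2x2, arcmin^2, axes
#'   x then y), `orientation` (major-axis angle, deg in [0, 180)),
#'   `aspect` (sqrt of the eigenvalue ratio, >= 1), `area` (arcmin^2 of the
#'   1-sigma ellipse, `pi sqrt(det Sigma)`), `equivalentDiameter` (arcmin),
#'   `amplitude`, `condition`, and `inverted = TRUE`.
#' @export
fitPoolingEllipse <- function(diffMap) {
  stopifnot(inherits(diffMap, "TiltDiffMap"))
  d <- diffMap$meanAbsDiff
  ok <- is.finite(d) & diffMap$nPairs > 0
  if (sum(ok) < 25)
    stop("fitPoolingEllipse: need at least 5x5 valid offsets")
  if (diff(range(d[ok])) <= 0)
    stop("fitPoolingEllipse: difference map is constant; fit is degenerate")
  DX <- matrix(diffMap$dx, length(diffMap$dy), length(diffMap$dx),
               byrow = TRUE)
  DY <- matrix(diffMap$dy, length(diffMap$dy), length(diffMap$dx))
  s <- max(d[ok]) - d
  x <- DX[ok]; y <- DY[ok]; sv <- s[ok]
  cell <- mean(diff(diffMap$dx)) * mean(diff(diffMap$dy))
  sv <- sv / (sum(sv) * cell)          # unit volume
  # moment-matched init
  w <- sv / sum(sv)
  S0 <- matrix(c(sum(w * x^2), sum(w * x * y), sum(w * x * y),
                 sum(w * y^2)), 2, 2)
  P0 <- tryCatch(solve(S0), error = function(e) diag(2) / mean(diag(S0)))
  U0 <- tryCatch(chol(P0), error = function(e) diag(sqrt(diag(P0))))
  # precision = U'U with U upper triangular: PD by construction
  par0 <- c(log(max(sv)), log(U0[1, 1]), U0[1, 2], log(U0[2, 2]))
  ssr <- function(p) {
    u11 <- exp(p[2]); u12 <- p[3]; u22 <- exp(p[4])
    q <- (u11 * x + u12 * y)^2 + (u22 * y)^2
    sum((sv - exp(p[1]) * exp(-q / 2))^2)
  }
  fit <- stats::optim(par0, ssr, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- fit$par
  U <- matrix(c(exp(p[2]), 0, p[3], exp(p[4])), 2, 2)
  Sigma <- solve(t(U) %*% U)
  ev <- eigen(Sigma, symmetric = TRUE)
  if (any(ev$values <= 0))
    stop("fitPoolingEllipse: fitted covariance is not positive definite")
  v <- ev$vectors[, 1]
  structure(list(covariance = Sigma,
                 orientation = (atan2(v[2], v[1]) / DEG) %% 180,
                 aspect = sqrt(ev$values[1] / ev$values[2]),
                 area = pi * sqrt(det(Sigma)),
                 equivalentDiameter = equivalentDiameter(pi * sqrt(det(Sigma))),
                 amplitude = exp(p[1]), condition = diffMap$condition,
                 inverted = TRUE),
            class = "EllipseFit")
}

#' Equivalent diameter of an ellipse
#'
#' The diameter of the circle with the same area: `D = 2 sqrt(A / pi)`.
#'
#' @param area ellipse area (arcmin^2).
#' @return arcmin.
#' @export
equivalentDiameter <- function(area) 2 * sqrt(area / pi)

#' Build a per-tilt pooling specification from ellipse fits
#'
#' Collects one [fitPoolingEllipse()] result per target-tilt bin into a
#' [PoolingSpec-class]: relative areas normalized to mean 1, per-bin aspect
#' ratios, and orientations set by the configured rule — "orthogonal"
#' (major axis orthogonal to the target tilt, the default suggested by the
#' scene statistics: for a target tilt of 0 the similar-tilt region is
#' elongated vertically), "aligned" (major axis along the tilt), or
#' "fitted" (each fit's own major-axis orientation).  The average
#' equivalent diameter is computed from the arithmetic mean of the fitted
#' areas.
#'
#' @param fits list of `EllipseFit` objects, one per bin, in bin order
#'   (bins `0:(nBins-1)`); missing bins are an error.
#' @param orientationRule "orthogonal", "aligned", or "fitted".
#' @param nBins number of tilt bins (default 24).
#' @return A [PoolingSpec-class].
#' @export
poolingSpecFromStats <- function(fits, orientationRule = c("orthogonal",
                                                           "aligned",
                                                           "fitted"),
                                 nBins = 24L) {
  orientationRule <- match.arg(orientationRule)
  if (length(fits) != nBins)
    stop("poolingSpecFromStats: need one fit per bin (",
         nBins - length(fits), " missing)")
  areas <- vapply(fits, function(f) f$area, numeric(1))
  aspects <- vapply(fits, function(f) f$aspect, numeric(1))
  fittedOri <- vapply(fits, function(f) f$orientation, numeric(1))
  centers <- tiltBinCenter(0:(nBins - 1), nBins)
  ori <- switch(orientationRule,
                orthogonal = (centers + 90) %% 180,
                aligned = centers %% 180,
                fitted = fittedOri)
  tab <- data.frame(bin = 0:(nBins - 1), tiltCenter = centers,
                    relArea = areas / mean(areas), aspect = aspects,
                    orientation = ori)
  new("PoolingSpec", table = tab,
      fittedDbar = equivalentDiameter(mean(areas)),
      orientationRule = orientationRule)
}

#' A PoolingSpec of identical circles
#'
#' Degenerate specification (relative area 1, aspect 1 everywhere) under
#' which adaptive elliptical pooling reduces exactly to fixed circular
#' pooling; useful as a reference and in tests.
#'
#' @param nBins number of tilt bins.
#' @param dBar nominal average equivalent diameter, arcmin.
#' @return A [PoolingSpec-class].
#' @export
isotropicPoolingSpec <- function(nBins = 24L, dBar = 60) {
  centers <- tiltBinCenter(0:(nBins - 1), nBins)
  tab <- data.frame(bin = 0:(nBins - 1), tiltCenter = centers,
                    relArea = rep(1, nBins), aspect = rep(1, nBins),
                    orientation = rep(0, nBins))
  new("PoolingSpec", table = tab, fittedDbar = dBar,
      orientationRule = "orthogonal")
}
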