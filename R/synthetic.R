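# Synthetic stereo scenes with analytic groundtruth.
#
# The generator emulates the structure of a natural stereo database: stereo
# pairs separated by a 6.5 cm inter-pupillary distance with co-registered
# range, no scene point nearer than 3 m, piecewise-smooth surfaces whose
# tilt distribution is cardinal-dominated, and tilt-dependent anisotropic
# spatial correlation (regions of similar tilt elongated according to a
# configurable rule, by default orthogonal to the tilt direction).

#' Default cardinal-peaked tilt prior (24 bins of 15 degrees)
#'
#' Sixty percent of the mass sits in the four bins containing the cardinal
#' tilts (0, 90, 180, 270); the remainder is spread evenly.
#'
#' @param cardinalMass total mass on the four cardinal bins.
#' @return numeric vector of 24 weights summing to 1.
#' @export
cardinalTiltPrior <- function(cardinalMass = 0.6) {
  w <- rep((1 - cardinalMass) / 20, 24)
  w[1 + c(0, 6, 12, 18)] <- cardinalMass / 4  # bins containing 0/90/180/270
  w / sum(w)
}

#' Recipe for a synthetic scene
#'
#' Bundles the generating conditions of [generateScene()].  Correlation
#' lengths set the full extents (major/minor axis) of the anisotropic
#' surface facets; the anisotropy rule maps a facet's tilt to the
#' orientation of its elongation ("orthogonal" to the tilt direction by
#' default, "aligned" with it, "isotropic", or a fixed angle in degrees).
#'
#' @param kind "planar_mosaic" (anisotropic Voronoi mosaic of planar
#'   facets), "ground_plus_objects" (receding ground plane with
#'   fronto-parallel objects), or "smooth_field" (smoothed random range
#'   field).
#' @param tiltPriorWeights 24-bin histogram of facet tilts; must sum to 1.
#' @param correlationLengthMajor,correlationLengthMinor facet extents in
#'   arcmin along the major/minor elongation axes.
#' @param anisotropyRule "orthogonal", "aligned", "isotropic", or a fixed
#'   orientation in degrees.
#' @param distanceRange facet centre distances, m (all >= 3).
#' @param slantRange facet slants, degrees.
#' @param textureElement texture element size (noise correlation length),
#'   arcmin.
#' @param textureContrast RMS contrast of the rendered texture (fraction).
#' @param shading logical; Lambertian shading under a fixed directional
#'   light, so the luminance cue carries tilt signal.
#' @param noiseSd independent pixel noise added to the right image,
#'   as a fraction of mean luminance.
#' @param nObjects number of fronto-parallel objects
#'   (kind "ground_plus_objects").
#' @param sizeRule optional function mapping a facet's tilt (degrees) to a
#'   multiplier on both correlation lengths, so the spatial scale of
#'   tilt coherence can vary with tilt (NULL = constant).
#' @param seed integer seed; the same recipe and seed give bit-identical
#'   scenes.
#' @return a `SceneRecipe` (classed list).
#' @export
sceneRecipe <- function(kind = c("planar_mosaic", "ground_plus_objects",
                                 "smooth_field"),
                        tiltPriorWeights = cardinalTiltPrior(),
                        correlationLengthMajor = 60,
                        correlationLengthMinor = 25,
                        anisotropyRule = "orthogonal",
                        distanceRange = c(5, 50),
                        slantRange = c(30, 60),
                        textureElement = 3,
                        textureContrast = 0.2,
                        shading = TRUE,
                        noiseSd = 0.01,
                        nObjects = 6,
                        sizeRule = NULL,
                        seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(correlationLengthMajor > 0, correlationLengthMinor > 0,
            correlationLengthMajor >= correlationLengthMinor,
            length(tiltPriorWeights) == 24,
            abs(sum(tiltPriorWeights) - 1) < 1e-8,
            min(distanceRange) >= 3)
  structure(list(kind = kind, tiltPriorWeights = tiltPriorWeights,
                 correlationLengthMajor = correlationLengthMajor,
                 correlationLengthMinor = correlationLengthMinor,
                 anisotropyRule = anisotropyRule,
                 distanceRange = distanceRange, slantRange = slantRange,
                 textureElement = textureElement,
                 textureContrast = textureContrast, shading = shading,
                 noiseSd = noiseSd, nObjects = nObjects,
                 sizeRule = sizeRule, seed = as.integer(seed)),
            class = "SceneRecipe")
}

.ellipseOrientation <- function(rule, tilt) {
  if (is.numeric(rule)) return(rep(rule %% 180, length(tilt)))
  switch(rule,
         orthogonal = (tilt + 90) %% 180,
         aligned = tilt %% 180,
         isotropic = rep(0, length(tilt)),
         stop("unknown anisotropy rule: ", rule))
}

# draw tilts from a 24-bin prior (uniform within the bin); bins are
# centred on the bin lower edges 0, 15, ..., i.e. bin b covers
# [15 b - 7.5, 15 b + 7.5), so cardinal tilts sit at bin centres
.drawTiltsFromPrior <- function(n, weights) {
  b <- sample.int(24, n, replace = TRUE, prob = weights) - 1L
  (b * 15 + stats::runif(n, -7.5, 7.5)) %% 360
}

# smoothed unit-variance noise field on an (ny, nx) grid (NA-free: the
# smoothing kernel is renormalized at the borders via a mask convolution)
.noiseField <- function(ny, nx, sigmaPx) {
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  if (sigmaPx >= 0.5) {
    k <- .gaussKernels(sigmaPx)
    sm <- function(m) {
      m0 <- m; m0[is.na(m0)] <- 0
      a <- .conv1(.conv1(m0, k$g, "y"), k$g, "x")
      w <- .conv1(.conv1(matrix(1, ny, nx), k$g, "y"), k$g, "x")
      a[is.na(a)] <- 0; w[is.na(w) | w <= 0] <- 1
      a / w
    }
    z <- sm(z)
  }
  (z - mean(z)) / stats::sd(z)
}

# bilinear interpolation of grid values g (ny, nx) at fractional
# coordinates (rows, cols), clamped to the grid
.bilinear <- function(g, rows, cols) {
  ny <- nrow(g); nx <- ncol(g)
  r <- pmin(pmax(rows, 1), ny); c <- pmin(pmax(cols, 1), nx)
  r0 <- pmin(floor(r), ny - 1); c0 <- pmin(floor(c), nx - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * ny + r0
  g[i00] * (1 - fr) * (1 - fc) + g[i00 + 1] * fr * (1 - fc) +
    g[i00 + ny] * (1 - fr) * fc + g[i00 + ny + 1] * fr * fc
}

# Anisotropic Voronoi assignment: each pixel joins the seed with minimal
# metric distance, the metric being elongated per-seed.  Seeds are bucketed
# into tiles so each pixel block only scans nearby candidates.
.assignFacets <- function(X, Y, seeds) {
  ny <- nrow(X); nx <- ncol(X)
  lab <- matrix(NA_integer_, ny, nx)
  best <- matrix(Inf, ny, nx)
  reach <- 2.5 * max(seeds$maj)  # arcmin; safe candidate radius
  bs <- 48L                      # block size, px
  for (bi in seq(1L, ny, by = bs)) {
    ri <- bi:min(bi + bs - 1L, ny)
    for (bj in seq(1L, nx, by = bs)) {
      cj <- bj:min(bj + bs - 1L, nx)
      xr <- range(X[ri, cj]); yr <- range(Y[ri, cj])
      cand <- which(seeds$x >= xr[1] - reach & seeds$x <= xr[2] + reach &
                    seeds$y >= yr[1] - reach & seeds$y <= yr[2] + reach)
      if (!length(cand)) cand <- seq_along(seeds$x)
      px <- as.numeric(X[ri, cj]); py <- as.numeric(Y[ri, cj])
      bb <- rep(Inf, length(px)); ll <- rep(NA_integer_, length(px))
      for (k in cand) {
        dxk <- px - seeds$x[k]; dyk <- py - seeds$y[k]
        cphi <- cos(seeds$phi[k] * DEG); sphi <- sin(seeds$phi[k] * DEG)
        u <- (cphi * dxk + sphi * dyk) / (seeds$maj[k] / 2)
        v <- (-sphi * dxk + cphi * dyk) / (seeds$min[k] / 2)
        d2 <- u * u + v * v
        hit <- d2 < bb
        bb[hit] <- d2[hit]; ll[hit] <- k
      }
      lab[ri, cj] <- ll; best[ri, cj] <- bb
    }
  }
  lab
}

#' Generate a synthetic RangeScene with analytic groundtruth
#'
#' Builds a range map according to the recipe, records the analytic tilt and
#' slant where the recipe defines them in closed form, renders a textured
#' (and optionally shaded) left image with per-facet affine texture
#' compression consistent with the surface orientation, and synthesizes the
#' right image by warping the left horizontally by the groundtruth disparity
#' map (linear sub-pixel interpolation), flagging fold-over pixels as
#' half-occluded and adding independent pixel noise.
#'
#' @param recipe a [sceneRecipe()].
#' @param geometry a [ViewingGeometry-class].
#' @param render logical; if FALSE, skip image rendering (range and
#'   groundtruth only), which is much faster when only tilt statistics are
#'   needed.
#' @return A [RangeScene-class] whose `groundtruth` slot holds the analytic
#'   [TiltMap-class] and whose `halfOcclusion` slot flags fold-over pixels.
#' @export
generateScene <- function(recipe, geometry, render = TRUE) {
  stopifnot(inherits(recipe, "SceneRecipe"))
  set.seed(recipe$seed)
  ny <- geometry@imageSize[1]; nx <- geometry@imageSize[2]
  ps <- geometry@pixelScale
  xa <- (seq_len(nx) - (nx + 1) / 2) * ps   # arcmin, centred
  ya <- (seq_len(ny) - (ny + 1) / 2) * ps
  X <- matrix(xa, ny, nx, byrow = TRUE)
  Y <- matrix(ya, ny, nx)

  out <- switch(recipe$kind,
    planar_mosaic = .genMosaic(recipe, X, Y),
    ground_plus_objects = .genGround(recipe, X, Y),
    smooth_field = .genSmooth(recipe, X, Y, ps))
  rng <- out$range
  if (min(rng, na.rm = TRUE) < 3)
    stop("generateScene: recipe/geometry inconsistency: scene point nearer ",
         "than 3 m (min range ", format(min(rng, na.rm = TRUE)), ")")

  gt <- NULL
  if (!is.null(out$tilt))
    gt <- TiltMap(tiltSigned = out$tilt, slant = out$slant,
                  definedMask = out$defined)

  if (!render) {
    blank <- matrix(1, ny, nx)
    scene <- RangeScene(rng, blank, blank, geometry, groundtruth = gt,
                        facetLabels = out$lab)
    if (is.null(gt))
      scene@groundtruth <- tiltFromRange(scene)
    return(scene)
  }

  left <- .renderLeft(recipe, out, X, Y, ps)
  scene0 <- RangeScene(rng, left, left, geometry, groundtruth = gt)
  dArcmin <- disparityFromRange(scene0)
  warp <- .warpRight(left, dArcmin / ps)
  right <- warp$right +
    stats::rnorm(ny * nx, sd = recipe$noiseSd * mean(left))
  scene <- RangeScene(rng, left, right, geometry, groundtruth = gt,
                      halfOcclusion = warp$occluded, facetLabels = out$lab)
  if (is.null(gt)) scene@groundtruth <- tiltFromRange(scene)
  scene
}

#' Facet-interior mask of a synthetic scene
#'
#' TRUE at pixels whose whole square neighborhood of half-width `marginPx`
#' lies on a single facet — the pixels whose image cues and range gradients
#' are uncontaminated by facet creases or depth boundaries.
#'
#' @param scene a synthetic [RangeScene-class] (with facet labels).
#' @param marginPx erosion half-width in pixels (use the operator's kernel
#'   radius, e.g. `ceiling(3 * sigma / pixelScale)`).
#' @return logical matrix.
#' @export
facetInterior <- function(scene, marginPx = 5L) {
  lab <- scene@facetLabels
  if (is.null(lab)) stop("facetInterior: scene has no facet labels")
  ny <- nrow(lab); nx <- ncol(lab)
  ok <- matrix(TRUE, ny, nx)
  m <- as.integer(marginPx)
  for (dy in -m:m) for (dx in -m:m) {
    if (dy == 0 && dx == 0) next
    sh <- matrix(NA_integer_, ny, nx)
    rt <- max(1, 1 - dy):min(ny, ny - dy)
    ct <- max(1, 1 - dx):min(nx, nx - dx)
    sh[rt, ct] <- lab[rt + dy, ct + dx]
    ok <- ok & !is.na(sh) & sh == lab
  }
  ok
}

.genMosaic <- function(recipe, X, Y) {
  areaA <- diff(range(X)) * diff(range(Y))
  cellA <- pi * (recipe$correlationLengthMajor / 2) *
    (recipe$correlationLengthMinor / 2)
  nSeeds <- max(4L, round(areaA / cellA))
  seeds <- list(x = stats::runif(nSeeds, min(X), max(X)),
                y = stats::runif(nSeeds, min(Y), max(Y)))
  seeds$tilt <- .drawTiltsFromPrior(nSeeds, recipe$tiltPriorWeights)
  sizeMul <- if (is.null(recipe$sizeRule)) rep(1, nSeeds) else
    vapply(seeds$tilt, recipe$sizeRule, numeric(1))
  seeds$slant <- stats::runif(nSeeds, recipe$slantRange[1],
                              recipe$slantRange[2])
  # facet distances follow a smooth base depth field so facet boundaries
  # are creases in a piecewise-smooth surface, not large depth steps.  The
  # base field is a ground-like surface whose (log-range) gradient is
  # slant-consistent — tan(sigma_base) per radian of visual angle — so
  # facet-to-facet depth steps are commensurate with within-facet slopes;
  # the scene's mean distance is drawn log-uniform over distanceRange
  # (depth variation WITHIN a few degrees of visual field is small in
  # real scenes; the distance range is spanned across scenes).
  dlo <- log(recipe$distanceRange[1] * 1.15)
  dhi <- log(recipe$distanceRange[2] / 1.15)
  r0mid <- if (dhi <= dlo) exp(mean(log(recipe$distanceRange))) else
    exp(stats::runif(1, dlo, dhi))
  sigmaBase <- stats::runif(1, 30, 60)
  baseSlope <- tan(sigmaBase * DEG) / ARCMIN_PER_RAD   # per arcmin, log scale
  spanY <- diff(range(Y))
  phase <- stats::runif(2, 0, 2 * pi)
  wobAmp <- 0.25 * baseSlope * spanY / (2 * pi)
  wob <- function(x, y) wobAmp * sin(2 * pi * x / spanY + phase[1]) +
    wobAmp * sin(2 * pi * y / spanY + phase[2])
  baseR <- function(x, y) pmin(pmax(
    r0mid * exp(baseSlope * y + wob(x, y)),
    recipe$distanceRange[1]), recipe$distanceRange[2])
  seeds$r0 <- baseR(seeds$x, seeds$y)
  seeds$phi <- .ellipseOrientation(recipe$anisotropyRule, seeds$tilt)
  if (identical(recipe$anisotropyRule, "isotropic")) {
    m <- sqrt(recipe$correlationLengthMajor * recipe$correlationLengthMinor)
    seeds$maj <- m * sizeMul; seeds$min <- m * sizeMul
  } else {
    seeds$maj <- recipe$correlationLengthMajor * sizeMul
    seeds$min <- recipe$correlationLengthMinor * sizeMul
  }
  lab <- .assignFacets(X, Y, seeds)
  tilt <- seeds$tilt[lab]; slant0 <- seeds$slant[lab]
  r0 <- seeds$r0[lab]
  dx <- X - seeds$x[lab]; dy <- Y - seeds$y[lab]
  # planar facet: range is affine in visual angle with gradient magnitude
  # r0 tan(slant) per radian along the tilt direction
  gmag <- r0 * tan(slant0 * DEG) / ARCMIN_PER_RAD   # m per arcmin
  # facets bow gently along their tilt direction (range quadratic in the
  # along-tilt coordinate u): the gradient direction, hence the analytic
  # tilt, is unchanged, while slant and shading vary smoothly within each
  # facet, so the luminance cue carries tilt signal as it does on real
  # curved surfaces.  The curvature is capped so the gradient never
  # reverses (tilt stays exact everywhere on the facet).
  u <- cos(tilt * DEG) * dx + sin(tilt * DEG) * dy   # arcmin, along tilt
  uscale <- recipe$correlationLengthMajor / 2
  curv <- 0.4 * gmag / (2 * uscale)
  gradU <- pmax(gmag + 2 * curv * u, 0.2 * gmag)     # m per arcmin, along u
  rng <- r0 + gmag * u + curv * u^2
  rng <- pmax(rng, 3.001)   # facets are small; clamp guards the far tails
  dim(rng) <- dim(X)
  slant <- atan(gradU * ARCMIN_PER_RAD / rng) / DEG
  dim(slant) <- dim(X); dim(tilt) <- dim(X)
  list(range = rng, tilt = tilt %% 360, slant = slant,
       defined = matrix(TRUE, nrow(X), ncol(X)), lab = lab,
       seedTilt = seeds$tilt, seedSlant = seeds$slant,
       sx = seeds$x, sy = seeds$y)
}

.genGround <- function(recipe, X, Y) {
  r0 <- mean(recipe$distanceRange)
  slant0 <- mean(recipe$slantRange)
  gmag <- r0 * tan(slant0 * DEG) / ARCMIN_PER_RAD
  rng <- r0 + gmag * Y                       # tilt 90: range increases upward
  tilt <- matrix(90, nrow(X), ncol(X))
  slant <- atan(gmag * ARCMIN_PER_RAD / rng) / DEG
  defined <- matrix(TRUE, nrow(X), ncol(X))
  lab <- matrix(1L, nrow(X), ncol(X))
  for (k in seq_len(recipe$nObjects)) {
    cx <- stats::runif(1, min(X), max(X)); cy <- stats::runif(1, min(Y), max(Y))
    hw <- stats::runif(1, 20, 60); hh <- stats::runif(1, 20, 60)
    rk <- stats::runif(1, max(4, recipe$distanceRange[1] - 1), r0)
    inObj <- abs(X - cx) <= hw & abs(Y - cy) <= hh
    rng[inObj] <- rk
    slant[inObj] <- 0
    defined[inObj] <- FALSE    # fronto-parallel: tilt undefined
    tilt[inObj] <- NA_real_
    lab[inObj] <- k + 1L
  }
  rng <- pmax(rng, 3.001)
  list(range = rng, tilt = tilt, slant = slant, defined = defined, lab = lab)
}

.genSmooth <- function(recipe, X, Y, ps) {
  sigPx <- mean(c(recipe$correlationLengthMajor,
                  recipe$correlationLengthMinor)) / 2 / ps
  z <- .noiseField(nrow(X), ncol(X), sigPx)
  r0 <- mean(recipe$distanceRange)
  # amplitude chosen so typical slants land mid slant-range
  amp <- r0 * tan(mean(recipe$slantRange) * DEG) *
    (sigPx * ps / ARCMIN_PER_RAD)
  rng <- pmax(r0 + amp * z, 3.001)
  # no closed-form tilt: groundtruth is computed from the emitted range map
  list(range = rng, tilt = NULL, slant = NULL, defined = NULL,
       lab = matrix(1L, nrow(X), ncol(X)))
}

# textured + shaded left image.  Texture coordinates are expanded along the
# tilt direction by 1/cos(slant), so the rendered texture is foreshortened
# consistently with the surface orientation.
.renderLeft <- function(recipe, out, X, Y, ps) {
  ny <- nrow(X); nx <- ncol(X)
  if (!is.null(out$tilt)) {
    tilt <- out$tilt; slant <- out$slant
    tilt[is.na(tilt)] <- 0
    slant[is.na(slant)] <- 0
  } else {
    tilt <- matrix(0, ny, nx); slant <- matrix(0, ny, nx)
  }
  ct <- cos(tilt * DEG); st <- sin(tilt * DEG)
  stretch <- 1 / pmax(cos(slant * DEG), 0.2)
  u <- (ct * X + st * Y) * stretch
  v <- -st * X + ct * Y
  tx <- ct * u - st * v
  ty <- st * u + ct * v
  # noise-grid lookup in pixel units with margin for the stretch
  gx0 <- min(tx) - 2 * ps; gy0 <- min(ty) - 2 * ps
  gnx <- ceiling((max(tx) - gx0) / ps) + 3L
  gny <- ceiling((max(ty) - gy0) / ps) + 3L
  noise <- .noiseField(gny, gnx, recipe$textureElement / ps)
  tex <- .bilinear(noise, (ty - gy0) / ps + 1, (tx - gx0) / ps + 1)
  dim(tex) <- c(ny, nx)
  lum <- 1 + recipe$textureContrast * tex
  if (isTRUE(recipe$shading)) {
    # Lambertian under a fixed directional light; surface normal from
    # (tilt, slant) with z toward the viewer
    l <- c(0.35, 0.45, 0.82); l <- l / sqrt(sum(l^2))
    nz <- cos(slant * DEG); nr <- sin(slant * DEG)
    shade <- pmax(nr * ct * l[1] + nr * st * l[2] + nz * l[3], 0)
    lum <- lum * (0.35 + 0.65 * shade)
  }
  pmax(lum, 0.01)
}

# horizontal warp of the left image by the disparity map (in px):
# right(x) = left(x + d).  Fold-over (non-monotonic sampling) pixels are
# half-occluded.
.warpRight <- function(left, dPx) {
  ny <- nrow(left); nx <- ncol(left)
  right <- left
  occ <- matrix(FALSE, ny, nx)
  js <- seq_len(nx)
  for (i in seq_len(ny)) {
    s <- js + dPx[i, ]
    right[i, ] <- stats::spline(js, left[i, ], xout = pmin(pmax(s, 1), nx),
                                method = "natural")$y
    ds <- c(diff(s), 1)
    occ[i, ] <- ds <= 0.05
  }
  list(right = right, occluded = occ)
}

#' Simulate an observer's tilt responses
#'
#' A parametric stand-in for human response tables: with probability
#' `lapseProb` the response is uniform on the circle; otherwise it is the
#' groundtruth tilt plus wrapped-Gaussian noise of variance `1/concentration`
#' (rad^2), shifted toward the nearest cardinal tilt by a gain
#' `cardinalAttraction`, with its sign flipped (180 added) with probability
#' `signFlipProb`.
#'
#' @param groundtruthTilts degrees in [0, 360).
#' @param concentration inverse circular variance of the response noise;
#'   `Inf` gives noiseless responses.
#' @param cardinalAttraction gain in [0, 1] pulling responses toward the
#'   nearest cardinal tilt.
#' @param signFlipProb,lapseProb probabilities in [0, 1].
#' @param seed integer seed.
#' @return data.frame with `stimulus`, `groundtruth`, `response` (degrees in
#'   [0, 360)).
#' @export
simulateObserver <- function(groundtruthTilts, concentration = 8,
                             cardinalAttraction = 0.3, signFlipProb = 0.02,
                             lapseProb = 0.01, seed = 1L) {
  stopifnot(concentration >= 0, cardinalAttraction >= 0,
            cardinalAttraction <= 1,
            signFlipProb >= 0, signFlipProb <= 1,
            lapseProb >= 0, lapseProb <= 1)
  set.seed(as.integer(seed))
  n <- length(groundtruthTilts)
  sdDeg <- if (is.infinite(concentration)) 0 else
    sqrt(1 / concentration) / DEG
  resp <- (groundtruthTilts + stats::rnorm(n, sd = sdDeg)) %% 360
  card <- (round(resp / 90) * 90) %% 360
  resp <- (resp + cardinalAttraction * circDiff(card, resp)) %% 360
  flip <- stats::runif(n) < signFlipProb
  resp[flip] <- (resp[flip] + 180) %% 360
  lapse <- stats::runif(n) < lapseProb
  resp[lapse] <- stats::runif(sum(lapse), 0, 360)
  data.frame(stimulus = seq_len(n), groundtruth = groundtruthTilts,
             response = resp)
}
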