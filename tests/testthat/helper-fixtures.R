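# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fxGeom <- function(ps = 2, npx = 128, fix = 10) {
  ViewingGeometry(ps, c(npx, npx), fixationDistance = fix)
}

# rendered mosaic scene at default recipe conditions (cached by seed)
fxScene <- function(seed, ps = 2, npx = 128) {
  key <- sprintf("scene_%d_%g_%d", seed, ps, npx)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generateScene(sceneRecipe(seed = seed),
                                fxGeom(ps, npx))
  .fx[[key]]
}

fxCues <- function(seed, ps = 2, npx = 128) {
  key <- sprintf("cues_%d_%g_%d", seed, ps, npx)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- computeCueMaps(fxScene(seed, ps, npx))
  .fx[[key]]
}

# brute-force circular mean: coarse-to-fine grid search minimizing the
# weighted mean (1 - cos) distance, final resolution 0.01 deg
gridCircMean <- function(angles, weights = rep(1, length(angles))) {
  obj <- function(th) {
    vapply(th, function(t)
      sum(weights * (1 - cos((t - angles) * pi / 180))), numeric(1))
  }
  coarse <- seq(0, 359.9, by = 0.1)
  t0 <- coarse[which.min(obj(coarse))]
  fine <- seq(t0 - 0.2, t0 + 0.2, by = 0.01)
  (fine[which.min(obj(fine))]) %% 360
}

# direct dense 2D convolution oracle (valid region only)
denseConv2 <- function(m, kern2) {
  kr <- (nrow(kern2) - 1) / 2; kc <- (ncol(kern2) - 1) / 2
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(NA_real_, ny, nx)
  for (i in (kr + 1):(ny - kr))
    for (j in (kc + 1):(nx - kc))
      out[i, j] <- sum(m[(i - kr):(i + kr), (j - kc):(j + kc)] *
                         kern2[nrow(kern2):1, ncol(kern2):1])
  out
}

# single analytic plane scene: range affine in visual angle
planeScene <- function(tau, slant, r0 = 10, geom = fxGeom(2, 96)) {
  ny <- geom@imageSize[1]; nx <- geom@imageSize[2]
  ps <- pixelScale(geom)
  X <- matrix((seq_len(nx) - (nx + 1) / 2) * ps, ny, nx, byrow = TRUE)
  Y <- matrix((seq_len(ny) - (ny + 1) / 2) * ps, ny, nx)
  g <- r0 * tan(slant * pi / 180) / (180 * 60 / pi)
  rng <- r0 + g * (cos(tau * pi / 180) * X + sin(tau * pi / 180) * Y)
  RangeScene(rng, matrix(1, ny, nx), matrix(1, ny, nx), geom)
}
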