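# Pooling regions and global estimation: geometry of the regions, the
# weighted circular pooling, degeneracy to the local model, and the
# benefit/harm structure of spatial averaging.

test_that("circular regions have the right pixel membership and weights", {
  geom <- fxGeom(2, 64)
  r0 <- circularRegion(0, geom)
  expect_equal(cbind(r0$dx, r0$dy), cbind(0L, 0L))
  expect_equal(r0$weights, 1)
  # pixel count approximates the disc area for d >= 10 px
  for (d in c(40, 80, 120)) {   # arcmin; 20/40/60 px diameter
    r <- circularRegion(d, geom)
    expected <- pi * (d / 2 / 2)^2
    expect_lt(abs(length(r$dx) / expected - 1), 0.05)
    expect_true(all(r$weights == r$weights[1]))
    expect_equal(sum(r$weights), 1)
  }
})

test_that("elliptical regions respect the spec and reduce to circles", {
  geom <- fxGeom(2, 64)
  iso <- isotropicPoolingSpec(dBar = 60)
  rc <- circularRegion(60, geom)
  re <- ellipticalRegion(123, 60, iso, geom)
  expect_setequal(paste(re$dx, re$dy), paste(rc$dx, rc$dy))
  # aspect 2 at tilt 0 with the orthogonal rule: vertical major axis
  tab <- poolingTable(iso)
  tab$aspect <- 2; tab$orientation <- (tab$tiltCenter + 90) %% 180
  spec2 <- new("PoolingSpec", table = tab, fittedDbar = 60,
               orientationRule = "orthogonal")
  rv <- ellipticalRegion(0, 60, spec2, geom)
  expect_gt(diff(range(rv$dy)), diff(range(rv$dx)))
  # average area across bins matches pi (dBar/2)^2 within lattice error
  areaPx <- mean(vapply(0:23, function(b)
    length(ellipticalRegion(tiltBinCenter(b), 60, spec2, geom)$dx),
    numeric(1)))
  expect_lt(abs(areaPx * 4 / (pi * 30^2) - 1), 0.05)
})

test_that("pooling is a weighted circular mean with documented fallbacks", {
  geom <- fxGeom(2, 64)
  reg <- circularRegion(20, geom)
  const <- matrix(77, 64, 64)
  expect_equal(poolEstimates(const, reg, c(32, 32))$estimate, 77)
  # single-pixel region returns the local estimate exactly
  set.seed(22)
  loc <- matrix(runif(64 * 64, 0, 360), 64, 64)
  r1 <- circularRegion(0, geom)
  expect_identical(poolEstimates(loc, r1, c(10, 11))$estimate, loc[10, 11])
  # brute-force weighted phasor oracle
  p <- poolEstimates(loc, reg, c(20, 20))
  v <- loc[cbind(20 + reg$dy, 20 + reg$dx)]
  ref <- (atan2(sum(sin(v * pi / 180)), sum(cos(v * pi / 180))) * 180 / pi) %% 360
  expect_lt(circAbsDiff(p$estimate, ref), 1e-9)
  # undefined pixels are dropped, weights renormalized
  loc2 <- loc; loc2[19:21, 19:21] <- NA; loc2[20, 20] <- 123
  expect_false(is.na(poolEstimates(loc2, reg, c(20, 20))$estimate))
  # no defined estimates -> undefined
  locNA <- matrix(NA_real_, 64, 64)
  expect_true(is.na(poolEstimates(locNA, reg, c(32, 32))$estimate))
  # degenerate resultant -> fall back to the target's local estimate:
  # a 5-pixel plus-shaped region holding the 5th roots of unity
  anti <- matrix(NA_real_, 64, 64)
  anti[30, 30] <- 0
  anti[29, 30] <- 72; anti[31, 30] <- 144
  anti[30, 29] <- 216; anti[30, 31] <- 288
  pd <- poolEstimates(anti, circularRegion(4.1, geom), c(30, 30))
  expect_true(pd$fallback)
  expect_equal(pd$estimate, 0)
})

test_that("diameter zero reproduces the local model exactly everywhere", {
  geom <- fxGeom(2, 64)
  set.seed(23)
  loc <- matrix(runif(64 * 64, 0, 360), 64, 64)
  tg <- cbind(sample(5:60, 40, TRUE), sample(5:60, 40, TRUE))
  g <- estimateGlobal(loc, geom, tg, mode = "fixed", diameter = 0)
  expect_identical(g, loc[tg])
  # adaptive with an isotropic spec matches fixed at the same diameter
  iso <- isotropicPoolingSpec(dBar = 40)
  gf <- estimateGlobal(loc, geom, tg, mode = "fixed", diameter = 40)
  ga <- estimateGlobal(loc, geom, tg, mode = "adaptive", diameter = 40,
                       spec = iso, keyMode = "local_estimate")
  expect_equal(ga, gf)
})

test_that("pooling shows the noise-averaging vs signal-blurring tradeoff", {
  # patchwise-constant tilt with iid circular noise: error dips at an
  # interior diameter, then rises past the patch scale
  geom <- fxGeom(4, 160)
  set.seed(24)
  diams <- c(0, 16, 32, 64, 128, 200)
  errs <- matrix(0, 4, length(diams))
  for (s in 1:4) {
    sc <- generateScene(sceneRecipe(anisotropyRule = "isotropic",
                                    correlationLengthMajor = 60,
                                    correlationLengthMinor = 60,
                                    seed = 30 + s), geom, render = FALSE)
    gt <- tiltSigned(groundtruth(sc))
    loc <- (gt + rnorm(length(gt), sd = 40)) %% 360
    dim(loc) <- dim(gt)
    tg <- cbind(sample(30:130, 120, TRUE), sample(30:130, 120, TRUE))
    for (di in seq_along(diams))
      errs[s, di] <- mean(circAbsDiff(
        estimateGlobal(loc, geom, tg, diameter = diams[di]), gt[tg]))
  }
  e <- colMeans(errs)
  k <- which.min(e)
  expect_gt(k, 1); expect_lt(k, length(diams))  # interior argmin
  expect_lt(e[k], e[1])                          # pooling beats local
  expect_gt(e[length(diams)], e[k])              # over-pooling hurts
  # spatially white tilt: any pooling degrades performance
  wt <- matrix(runif(160 * 160, 0, 360), 160, 160)
  locw <- (wt + rnorm(160 * 160, sd = 30)) %% 360
  dim(locw) <- dim(wt)
  tg <- cbind(sample(30:130, 150, TRUE), sample(30:130, 150, TRUE))
  e0 <- mean(circAbsDiff(estimateGlobal(locw, geom, tg, diameter = 0), wt[tg]))
  for (d in c(16, 40)) {
    ed <- mean(circAbsDiff(estimateGlobal(locw, geom, tg, diameter = d),
                           wt[tg]))
    expect_gt(ed, e0)
  }
})
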