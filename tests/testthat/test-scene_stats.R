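# Spatial tilt statistics: prior histograms, difference maps, and the
# Gaussian ellipse fits.

test_that("tilt prior histogram is normalized and finds delta/cardinal structure", {
  tm <- TiltMap(tiltSigned = matrix(45, 20, 20), slant = matrix(40, 20, 20),
                definedMask = matrix(TRUE, 20, 20))
  h <- tiltPriorHistogram(tm)
  expect_equal(sum(h$p), 1)
  expect_equal(h$p[h$bin == tiltBin(45)], 1)
  # uniform field is flat within multinomial error
  set.seed(16)
  tu <- TiltMap(tiltSigned = matrix(runif(1e4, 0, 360), 100, 100),
                slant = matrix(40, 100, 100),
                definedMask = matrix(TRUE, 100, 100))
  hu <- tiltPriorHistogram(tu)
  expect_true(all(abs(hu$count - 1e4 / 24) < 5 * sqrt(1e4 / 24)))
  # cardinal-peaked recipe puts its peaks at the cardinal bins
  sc <- generateScene(sceneRecipe(seed = 17), fxGeom(4, 160), render = FALSE)
  hc <- tiltPriorHistogram(groundtruth(sc))
  cardinalBins <- c(0, 6, 12, 18)
  expect_gt(sum(hc$p[hc$bin %in% cardinalBins]), 0.4)
  top4 <- order(hc$p, decreasing = TRUE)[1:4]
  expect_setequal(hc$bin[top4], cardinalBins)
})

test_that("difference maps are zero at the origin and symmetric under exchange", {
  sc <- generateScene(sceneRecipe(seed = 18), fxGeom(4, 128), render = FALSE)
  dm <- meanDiffMap(groundtruth(sc), fxGeom(4, 128), maxOffset = 24)
  ctr <- which(dm$dx == 0)
  expect_equal(dm$meanAbsDiff[ctr, ctr], 0)
  # unconditioned map: value(dx, dy) = value(-dx, -dy) exactly
  flipped <- dm$meanAbsDiff[rev(seq_along(dm$dy)), rev(seq_along(dm$dx))]
  expect_equal(dm$meanAbsDiff, flipped, tolerance = 1e-12)
})

test_that("difference maps hit the analytic values of degenerate fields", {
  geom <- fxGeom(2, 64)
  const <- TiltMap(tiltSigned = matrix(123, 64, 64),
                   slant = matrix(40, 64, 64),
                   definedMask = matrix(TRUE, 64, 64))
  dmc <- meanDiffMap(const, geom, maxOffset = 10)
  expect_true(all(dmc$meanAbsDiff[dmc$nPairs > 0] == 0))
  # iid uniform tilt: 90 at all nonzero offsets
  set.seed(19)
  unif <- TiltMap(tiltSigned = matrix(runif(300^2, 0, 360), 300, 300),
                  slant = matrix(40, 300, 300),
                  definedMask = matrix(TRUE, 300, 300))
  dmu <- meanDiffMap(unif, geom, maxOffset = 4)
  off <- dmu$meanAbsDiff[dmu$nPairs > 0 &
                           outer(dmu$dy != 0, dmu$dx != 0, "|")]
  expect_true(all(abs(off - 90) < 1))
})

test_that("ellipse fits recover constructed Gaussian covariances", {
  mkdm <- function(Sigma, R = 20, ps = 4) {
    o <- seq(-R, R) * ps
    DX <- matrix(o, length(o), length(o), byrow = TRUE)
    DY <- matrix(o, length(o), length(o))
    P <- solve(Sigma)
    s <- exp(-(P[1, 1] * DX^2 + 2 * P[1, 2] * DX * DY + P[2, 2] * DY^2) / 2)
    structure(list(dx = o, dy = o, meanAbsDiff = max(s) - s,
                   nPairs = matrix(1, length(o), length(o)),
                   condition = NULL, method = "phasor"),
              class = "TiltDiffMap")
  }
  rot <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  set.seed(20)
  for (i in 1:50) {
    th <- runif(1, 0, pi)
    lam <- sort(runif(2, 60, 600), decreasing = TRUE)
    S <- rot(th) %*% diag(lam) %*% t(rot(th))
    f <- fitPoolingEllipse(mkdm(S))
    expect_lt(norm(f$covariance - S, "F") / norm(S, "F"), 0.05)
    aspTrue <- sqrt(lam[1] / lam[2])
    if (aspTrue > 1.1) {
      expect_lt(circAbsDiff(f$orientation, (th * 180 / pi) %% 180, 180), 3)
      expect_lt(abs(f$aspect / aspTrue - 1), 0.05)
    }
  }
  # isotropic bowl: aspect ratio 1 within 0.05
  fi <- fitPoolingEllipse(mkdm(diag(c(200, 200))))
  expect_lt(abs(fi$aspect - 1), 0.05)
  # constant map is degenerate
  cm <- mkdm(diag(2) * 100)
  cm$meanAbsDiff[] <- 5
  expect_error(fitPoolingEllipse(cm), "constant")
})

test_that("equivalent diameter follows D = 2 sqrt(A/pi)", {
  expect_equal(equivalentDiameter(pi), 2)
  expect_equal(equivalentDiameter(pi * (7 / 2)^2), 7)
  # semi-axes (2, 0.5): area pi -> diameter 2
  expect_equal(equivalentDiameter(pi * 2 * 0.5), 2)
})

test_that("anisotropic generation is recovered by the ellipse fit", {
  geom <- ViewingGeometry(4, c(256, 256), fixationDistance = 10)
  genAngle <- 140
  sc <- generateScene(sceneRecipe(anisotropyRule = genAngle, seed = 21),
                      geom, render = FALSE)
  dm <- meanDiffMap(groundtruth(sc), geom, maxOffset = 60, step = 2)
  f <- fitPoolingEllipse(dm)
  expect_gt(f$aspect, 1.2)
  expect_lt(circAbsDiff(f$orientation, genAngle, 180), 10)
})

test_that("pooling specs assemble relative areas, rules, and scaling", {
  mkfit <- function(area, aspect, ori) {
    structure(list(covariance = diag(2), orientation = ori, aspect = aspect,
                   area = area, equivalentDiameter = equivalentDiameter(area),
                   amplitude = 1, condition = NULL, inverted = TRUE),
              class = "EllipseFit")
  }
  fits <- lapply(1:24, function(i) mkfit(100, 1.5, 10))
  spec <- poolingSpecFromStats(fits, "orthogonal")
  tab <- poolingTable(spec)
  expect_equal(tab$relArea, rep(1, 24))
  expect_equal(fittedDiameter(spec), equivalentDiameter(100))
  expect_equal(tab$orientation, (tab$tiltCenter + 90) %% 180)
  # target tilt 0 with the orthogonal rule: vertical major axis
  expect_equal(tab$orientation[tab$tiltCenter == 0], 90)
  aligned <- poolingSpecFromStats(fits, "aligned")
  expect_equal(poolingTable(aligned)$orientation,
               poolingTable(aligned)$tiltCenter %% 180)
  # doubling all areas doubles the mean area, diameter scales by sqrt(2)
  fits2 <- lapply(1:24, function(i) mkfit(200, 1.5, 10))
  expect_equal(fittedDiameter(poolingSpecFromStats(fits2, "orthogonal")),
               sqrt(2) * fittedDiameter(spec))
  expect_error(poolingSpecFromStats(fits[1:20], "orthogonal"), "per bin")
})

test_that("one-pass conditioned maps agree with per-bin single maps", {
  geom <- fxGeom(4, 96)
  sc <- generateScene(sceneRecipe(seed = 64), geom, render = FALSE)
  all24 <- meanDiffMapByTilt(groundtruth(sc), geom, maxOffset = 16)
  for (b in c(0, 6, 13)) {
    single <- meanDiffMap(groundtruth(sc), geom, maxOffset = 16,
                          condition = b)
    expect_identical(all24[[b + 1]]$nPairs, single$nPairs)
    expect_equal(all24[[b + 1]]$meanAbsDiff, single$meanAbsDiff,
                 tolerance = 1e-12)
  }
})
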