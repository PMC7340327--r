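# Evaluation machinery: error aggregation, diameter sweeps, bootstrap CIs,
# per-tilt best diameters, reliability diagnostics, consensus baseline.

test_that("mean tilt error matches its brute-force recomputation", {
  expect_equal(meanTiltError(c(10, 20), c(10, 20)), 0)
  # constant 30-deg errors: 30 under either aggregation
  est <- c(40, 130, 220); ref <- c(10, 100, 190)
  expect_equal(meanTiltError(est, ref), 30)
  expect_equal(meanTiltError(est, ref, "arithmetic"), 30)
  set.seed(28)
  a <- runif(300, 0, 360); b <- runif(300, 0, 360)
  d <- abs((a - b + 180) %% 360 - 180)
  ref1 <- (atan2(sum(sin(d * pi / 180)), sum(cos(d * pi / 180))) * 180 / pi) %% 360
  expect_lt(abs(meanTiltError(a, b) - ref1), 1e-9)
  expect_lt(abs(meanTiltError(a, b, "arithmetic") - mean(d)), 1e-9)
  expect_error(meanTiltError(NA_real_, 1), "no matched")
})

test_that("diameter sweeps anchor at the local model and are order-pure", {
  geom <- fxGeom(4, 96)
  set.seed(29)
  sc <- generateScene(sceneRecipe(anisotropyRule = "isotropic", seed = 40),
                      geom, render = FALSE)
  gt <- tiltSigned(groundtruth(sc))
  loc <- (gt + rnorm(length(gt), sd = 35)) %% 360; dim(loc) <- dim(gt)
  tg <- data.frame(scene = 1,
                   row = sample(20:76, 80, TRUE),
                   col = sample(20:76, 80, TRUE))
  tg$reference <- gt[cbind(tg$row, tg$col)]
  cv <- sweepDiameters(list(loc), geom, tg, c(0, 24, 48, 96))
  localErr <- meanTiltError(loc[cbind(tg$row, tg$col)], tg$reference)
  expect_equal(cv$meanError[cv$diameter == 0], localErr)
  # purity: a single-diameter sweep matches the same entry of the full sweep
  cv48 <- sweepDiameters(list(loc), geom, tg, 48)
  expect_equal(cv48$meanError, cv$meanError[cv$diameter == 48])
  # constant-patch ensemble: argmin at a strictly positive diameter
  expect_gt(cv$diameter[which.min(cv$meanError)], 0)
})

test_that("bootstrap CIs behave like percentile intervals should", {
  expect_equal(unlist(bootstrapCI(rep(12, 50), nSets = 200, seed = 1)[
    c("lower", "upper")]), c(12, 12), ignore_attr = TRUE)
  set.seed(30)
  for (i in 1:20) {
    e <- runif(60, 0, 90)
    ci <- bootstrapCI(e, nSets = 500, seed = i)
    expect_lte(ci$lower, ci$point + 1e-9)
    expect_gte(ci$upper, ci$point - 1e-9)
  }
  e <- runif(400, 0, 90)
  ciA <- bootstrapCI(e, nSets = 500, seed = 3)
  ciB <- bootstrapCI(e, nSets = 500, seed = 3)
  expect_identical(ciA, ciB)
  # CIs shrink with stimulus count (fixed seed family)
  w100 <- with(bootstrapCI(e[1:100], nSets = 800, seed = 4), upper - lower)
  w400 <- with(bootstrapCI(e, nSets = 800, seed = 4), upper - lower)
  expect_lt(w400, w100)
})

test_that("per-tilt best diameters track the generating correlation scale", {
  geom <- fxGeom(4, 160)
  # facets twice as large near horizontal tilts as near vertical ones
  rule <- function(t) if (circAbsDiff(t, 90, 180) < 45) 1.8 else 0.6
  set.seed(31)
  localMaps <- list(); keyMaps <- list(); tg <- NULL
  for (s in 1:6) {
    sc <- generateScene(sceneRecipe(sizeRule = rule,
                                    anisotropyRule = "isotropic",
                                    seed = 50 + s), geom, render = FALSE)
    gt <- tiltSigned(groundtruth(sc))
    loc <- (gt + rnorm(length(gt), sd = 40)) %% 360; dim(loc) <- dim(gt)
    localMaps[[s]] <- loc; keyMaps[[s]] <- gt
    cand <- which(!is.na(gt), arr.ind = TRUE)
    cand <- cand[cand[, 1] >= 25 & cand[, 1] <= 135 &
                   cand[, 2] >= 25 & cand[, 2] <= 135, ]
    bins <- tiltBin(gt[cand])
    keep <- unlist(lapply(0:23, function(b) {
      i <- which(bins == b); i[sample.int(length(i), min(40, length(i)))]
    }))
    tg <- rbind(tg, data.frame(scene = s, row = cand[keep, 1],
                               col = cand[keep, 2],
                               reference = gt[cand[keep, , drop = FALSE]]))
  }
  cv <- sweepDiameters(localMaps, geom, tg, c(8, 16, 32, 48, 72, 104))
  bins <- tiltBin(tg$reference)
  res <- bestDiameterPerTilt(cv, bins)
  genScale <- vapply(tiltBinCenter(res$table$bin), rule, numeric(1))
  expect_gt(cor(res$table$bestDiameter, genScale, method = "spearman"), 0)
  # with a matching reference the correlation is positive and significant
  res2 <- bestDiameterPerTilt(cv, bins, referenceDiameters = genScale * 40,
                              nPerm = 2000, seed = 2)
  expect_gt(res2$correlation, 0)
  expect_lt(res2$pValue, 0.05)
  # degenerate (zero-variance) references are flagged
  res3 <- bestDiameterPerTilt(cv, bins,
                              referenceDiameters = rep(40, 24), seed = 2)
  expect_true(res3$degenerate)
  expect_true(is.na(res3$correlation))
})

test_that("ties in the best-diameter argmin go to the smallest diameter", {
  curve <- data.frame(diameter = c(0, 10, 20), meanError = c(5, 5, 7), n = 3)
  attr(curve, "perTarget") <- matrix(c(5, 5, 5, 5, 7, 7), 2, 3)
  class(curve) <- c("ErrorCurve", class(curve))
  res <- bestDiameterPerTilt(curve, c(0, 0))
  expect_equal(res$table$bestDiameter, 0)
})

test_that("reliability conditionals normalize and detect shift invariance", {
  set.seed(32)
  gt <- runif(20000, 0, 360)
  # exact construction: estimate = groundtruth -> delta conditionals
  r0 <- reliabilityDiagnostic(gt, gt)
  ok <- !apply(r0$conditionals, 1, anyNA)
  expect_true(all(abs(rowSums(r0$conditionals[ok, ]) - 1) < 1e-12))
  # each 30-deg estimate bin straddles one full and two half 15-deg
  # groundtruth bins: all mass sits in those three
  top3 <- apply(r0$conditionals[ok, ], 1, function(p)
    sum(sort(p, decreasing = TRUE)[1:3]))
  expect_true(all(top3 > 0.999))
  # fixed circular noise: shift-invariant conditionals up to sampling error
  est <- (gt + rnorm(20000, sd = 20)) %% 360
  r1 <- reliabilityDiagnostic(est, gt)
  expect_lt(r1$shiftInvariance, 0.1)
  # tilt-dependent noise breaks shift invariance
  est2 <- (gt + rnorm(20000, sd = ifelse(gt < 180, 5, 80))) %% 360
  r2 <- reliabilityDiagnostic(est2, gt)
  expect_gt(r2$shiftInvariance, r1$shiftInvariance)
})

test_that("consensus baseline is the per-stimulus circular mean", {
  resp <- data.frame(stimulus = rep(1:3, each = 2),
                     observer = rep(c("a", "b"), 3),
                     response = c(80, 100, 10, 350, 200, 200))
  cons <- consensusBaseline(resp)
  expect_equal(cons$consensus[1], 90)
  expect_lt(circAbsDiff(cons$consensus[2], 0), 1e-9)
  expect_equal(cons$consensus[3], 200)
  # brute-force phasor oracle on random tables
  set.seed(33)
  rr <- data.frame(stimulus = rep(1:20, each = 4),
                   observer = rep(1:4, 20),
                   response = runif(80, 0, 360))
  cc <- consensusBaseline(rr)
  for (s in c(3, 11, 17)) {
    v <- rr$response[rr$stimulus == s]
    ref <- (atan2(sum(sin(v * pi / 180)), sum(cos(v * pi / 180))) * 180 / pi) %% 360
    expect_lt(circAbsDiff(cc$consensus[cc$stimulus == s], ref), 1e-9)
  }
  # degenerate opposed pair flagged as NA
  bad <- data.frame(stimulus = c(1, 1), observer = c("a", "b"),
                    response = c(0, 180))
  expect_true(is.na(consensusBaseline(bad)$consensus))
  expect_error(consensusBaseline(resp[1, ]), "2 observers")
})
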