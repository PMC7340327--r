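# Stage 1: the lookup-table Bayesian local estimator of signed tilt.
#
# Tilt magnitude is the conditional circular mean of unsigned groundtruth
# tilt given the quantized triplet of unsigned cues (luminance, texture,
# disparity); tilt sign is the sign of the conditional mean of signed tilt
# given the quantized signed disparity cue; the signed local estimate is
# their product.  The tables store phasor accumulators, so conditional
# means are exact sample statistics and tables merge associatively.

.emptyLookup <- function(nBins = 64L, method = "printed", meta = list()) {
  z3 <- array(0, c(nBins, nBins, nBins))
  new("TiltLookup", nBins = as.integer(nBins), cosU = z3, sinU = z3,
      countU = z3, cosS = numeric(nBins), sinS = numeric(nBins),
      countS = numeric(nBins), method = method, meta = meta)
}

#' Train lookup tables from binned training samples
#'
#' The low-level trainer: takes one row per training pixel with the three
#' unsigned cue bins, the signed disparity-cue bin, and the groundtruth
#' unsigned and signed tilts, and accumulates unit phasors into the
#' corresponding cells.  Accumulation is order-independent.
#'
#' @param samples data.frame with integer columns `lumBin`, `texBin`,
#'   `dispBin`, `dispSignedBin` (0-based, in `0:(nBins-1)`) and numeric
#'   `tiltUnsigned` (deg in [0, 180)), `tiltSigned` (deg in [0, 360)).
#' @param nBins bins per cue axis (default 64).
#' @param method "printed": unsigned-tilt phasors are accumulated at the
#'   raw angle and the conditional mean is reduced mod 180; "doubling":
#'   angles are doubled before accumulation and the mean halved (the
#'   standard orientation-statistics estimator).
#' @return A [TiltLookup-class].
#' @export
trainLookupFromBins <- function(samples, nBins = 64L,
                                method = c("printed", "doubling")) {
  method <- match.arg(method)
  need <- c("lumBin", "texBin", "dispBin", "dispSignedBin", "tiltUnsigned",
            "tiltSigned")
  stopifnot(all(need %in% names(samples)))
  if (nrow(samples) == 0L)
    stop("trainLookupFromBins: no defined training pixels")
  bins <- c(samples$lumBin, samples$texBin, samples$dispBin,
            samples$dispSignedBin)
  if (any(bins < 0L | bins >= nBins))
    stop("trainLookupFromBins: bin indices must lie in 0:(nBins-1)")
  lut <- .emptyLookup(nBins, method)
  mult <- if (method == "doubling") 2 else 1
  thU <- samples$tiltUnsigned * mult * DEG
  thS <- samples$tiltSigned * DEG
  idxU <- 1L + samples$lumBin + nBins * samples$texBin +
    nBins^2 * samples$dispBin
  accU <- rowsum(cbind(cos(thU), sin(thU), 1), group = idxU)
  iU <- as.integer(rownames(accU))
  lut@cosU[iU] <- accU[, 1]; lut@sinU[iU] <- accU[, 2]
  lut@countU[iU] <- accU[, 3]
  idxS <- 1L + samples$dispSignedBin
  accS <- rowsum(cbind(cos(thS), sin(thS), 1), group = idxS)
  iS <- as.integer(rownames(accS))
  lut@cosS[iS] <- accS[, 1]; lut@sinS[iS] <- accS[, 2]
  lut@countS[iS] <- accS[, 3]
  lut@meta <- list(nTrain = nrow(samples))
  lut
}

# binned training rows from co-registered cue and tilt maps
.binnedSamples <- function(cues, tilt, nBins = 64L) {
  ok <- definedMask(cues, "all") & definedMask(tilt)
  if (!any(ok)) return(NULL)
  data.frame(
    lumBin = quantizeCue(cueMap(cues, "lum_unsigned")[ok], nBins, 180),
    texBin = quantizeCue(cueMap(cues, "tex_unsigned")[ok], nBins, 180),
    dispBin = quantizeCue(cueMap(cues, "disp_unsigned")[ok], nBins, 180),
    dispSignedBin = quantizeCue(cueMap(cues, "disp_signed")[ok], nBins, 360),
    tiltUnsigned = tiltUnsigned(tilt)[ok],
    tiltSigned = tiltSigned(tilt)[ok])
}

#' Train lookup tables from scenes
#'
#' For every pixel where all cues and groundtruth tilt are defined (and the
#' pixel is not half-occluded), accumulates the unsigned-tilt phasor into
#' the (luminance, texture, disparity) cue cell and the signed-tilt phasor
#' into the signed-disparity cell.
#'
#' @param scenes list of `list(cues = CueMaps, tilt = TiltMap)` pairs.
#' @inheritParams trainLookupFromBins
#' @return A [TiltLookup-class].
#' @export
trainLookup <- function(scenes, nBins = 64L,
                        method = c("printed", "doubling")) {
  method <- match.arg(method)
  rows <- lapply(scenes, function(s) .binnedSamples(s$cues, s$tilt, nBins))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("trainLookup: no defined training pixels in any scene")
  trainLookupFromBins(do.call(rbind, rows), nBins, method)
}

#' Merge lookup tables trained on disjoint scene sets
#'
#' Exact phasor/count addition: training on the union of two scene sets
#' equals merging the tables trained on each.
#'
#' @param a,b [TiltLookup-class] objects with identical `nBins` and
#'   `method`.
#' @return A [TiltLookup-class].
#' @export
mergeLookup <- function(a, b) {
  stopifnot(a@nBins == b@nBins, a@method == b@method)
  a@cosU <- a@cosU + b@cosU; a@sinU <- a@sinU + b@sinU
  a@countU <- a@countU + b@countU
  a@cosS <- a@cosS + b@cosS; a@sinS <- a@sinS + b@sinS
  a@countS <- a@countS + b@countS
  a@meta <- list(nTrain = sum(unlist(c(a@meta["nTrain"], b@meta["nTrain"]))))
  a
}

# conditional unsigned means per cell, honoring the training method
.lutUnsignedMean <- function(lut, C, S, n) {
  if (lut@method == "doubling") {
    mu <- (atan2(S, C) / DEG / 2) %% 180
    mu[n <= 0] <- NA_real_
    mu
  } else {
    .meanFromSums(C, S, n, half = TRUE)
  }
}

#' Signed tilt sign from the signed-disparity table
#'
#' The sign of the conditional circular mean of signed tilt: +1 when the
#' mean's argument lies in [0, 180], -1 otherwise.  Cells with an exactly
#' degenerate resultant return +1 (with a warning at lookup time).
#' @keywords internal
.lutSign <- function(lut) {
  arg <- atan2(lut@sinS, lut@cosS) / DEG   # (-180, 180]
  s <- ifelse(arg >= 0, 1, -1)
  s[lut@countS <= 0] <- NA_real_
  s
}

#' Local signed tilt estimates from quantized cues
#'
#' Applies trained lookup tables: the unsigned-tilt conditional mean at the
#' pixel's (luminance, texture, disparity) cue cell, multiplied by the tilt
#' sign from the signed-disparity cell; sign -1 maps an unsigned estimate
#' `t` to `(-t) mod 360 = 360 - t`.  Pixels that hit an empty unsigned cell
#' back off to the marginal conditional mean over the disparity cue alone,
#' then to the global prior mean; the `provenance` map records which route
#' produced each estimate (0 full table, 1 disparity marginal, 2 prior,
#' NA undefined).
#'
#' @param cues a [CueMaps-class], or a data.frame of binned cues with
#'   columns `lumBin`, `texBin`, `dispBin`, `dispSignedBin`.
#' @param lut a trained [TiltLookup-class].
#' @return For a [CueMaps-class]: list with `tilt` (deg in [0, 360), NA
#'   undefined), `defined`, `provenance`.  For a data.frame: the same as
#'   vectors.
#' @export
estimateLocal <- function(cues, lut) {
  n <- lut@nBins
  if (is(cues, "CueMaps")) {
    ok <- definedMask(cues, "all")
    bins <- data.frame(
      lumBin = quantizeCue(cueMap(cues, "lum_unsigned")[ok], n, 180),
      texBin = quantizeCue(cueMap(cues, "tex_unsigned")[ok], n, 180),
      dispBin = quantizeCue(cueMap(cues, "disp_unsigned")[ok], n, 180),
      dispSignedBin = quantizeCue(cueMap(cues, "disp_signed")[ok], n, 360))
    est <- estimateLocal(bins, lut)
    tilt <- matrix(NA_real_, nrow(cues@lumSigned), ncol(cues@lumSigned))
    prov <- tilt
    tilt[ok] <- est$tilt
    prov[ok] <- est$provenance
    return(list(tilt = tilt, defined = ok & !is.na(tilt),
                provenance = prov))
  }
  idxU <- 1L + cues$lumBin + n * cues$texBin + n^2 * cues$dispBin
  muU <- .lutUnsignedMean(lut, lut@cosU, lut@sinU, lut@countU)[idxU]
  prov <- rep(0, length(idxU))
  # fallback 1: marginal over the unsigned disparity cue only
  if (anyNA(muU)) {
    margC <- apply(lut@cosU, 3, sum); margS <- apply(lut@sinU, 3, sum)
    margN <- apply(lut@countU, 3, sum)
    margMu <- .lutUnsignedMean(lut, margC, margS, margN)
    miss <- is.na(muU)
    muU[miss] <- margMu[cues$dispBin[miss] + 1L]
    prov[miss] <- 1
    # fallback 2: global prior mean
    if (anyNA(muU)) {
      priorMu <- .lutUnsignedMean(lut, sum(lut@cosU), sum(lut@sinU),
                                  sum(lut@countU))
      miss2 <- is.na(muU)
      muU[miss2] <- priorMu
      prov[miss2] <- 2
    }
  }
  sgn <- .lutSign(lut)[cues$dispSignedBin + 1L]
  if (anyNA(sgn)) {
    warning("estimateLocal: ", sum(is.na(sgn)),
            " pixels hit an empty sign cell; sign +1 used")
    sgn[is.na(sgn)] <- 1
  }
  tilt <- ifelse(sgn >= 0, muU, (-muU) %% 360)
  prov[is.na(tilt)] <- NA_real_
  list(tilt = tilt %% 360, defined = !is.na(tilt), provenance = prov)
}

#' Area-matched local control model
#'
#' The identical local pipeline with the cue space constant scaled so the
#' cue-support diameter (6 sigma: kernels are truncated at 3 sigma) matches
#' a configured value, by default 1 degree.  Serves as the control that
#' separates "pooling local estimates" from "computing cues over a larger
#' area": its estimates use the same image area as the best global model
#' but no second-stage pooling.
#'
#' @param scene a [RangeScene-class].
#' @param lutTrainScenes list of [RangeScene-class] training scenes (cues
#'   are recomputed at the enlarged sigma on these too, so training and
#'   testing match).
#' @param supportDiameter cue support diameter in degrees (default 1.0).
#' @param nBins,method,textureStep passed through to the cue and training
#'   steps.
#' @return list with `tilt`, `defined`, `provenance`, `sigmaCue` (arcmin),
#'   `lut`.
#' @export
areaMatchedLocal <- function(scene, lutTrainScenes, supportDiameter = 1.0,
                             nBins = 64L, method = "printed",
                             textureStep = 1L) {
  sigmaCue <- supportDiameter * 60 / 6
  train <- lapply(lutTrainScenes, function(s) {
    list(cues = computeCueMaps(s, sigmaCue = sigmaCue,
                               textureStep = textureStep),
         tilt = groundtruth(s))
  })
  lut <- trainLookup(train, nBins = nBins, method = method)
  cues <- computeCueMaps(scene, sigmaCue = sigmaCue,
                         textureStep = textureStep)
  est <- estimateLocal(cues, lut)
  c(est, list(sigmaCue = sigmaCue, lut = lut))
}
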