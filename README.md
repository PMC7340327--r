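# tiltpool

Hierarchical estimation of 3D surface tilt from stereo images, with
spatial pooling rules fit to the statistics of tilt in scenes.

## The problem

Estimating the 3D orientation of surfaces from 2D images is a core task
for biological and machine vision. Surface orientation is parameterized by
*slant* σ (rotation out of the frontoparallel plane, 0–90°) and *tilt* τ
(the direction of that rotation: the angle of the surface normal projected
into the frontoparallel plane; signed tilt ∈ [0°, 360°), unsigned tilt
∈ [0°, 180°)). Groundtruth tilt is the orientation of the range gradient,

    τ = atan2(∂r/∂y, ∂r/∂x),

computed from a range map **r** co-registered with the image (Gaussian
derivative operators, space constant σ_tilt = 3 arcmin), so a receding
ground plane has τ = 90°.

`tiltpool` implements a two-stage estimator of signed tilt:

1. **Local stage** — at each pixel, three unsigned cues are measured
   (luminance-gradient orientation, dominant texture orientation from the
   local amplitude spectrum, disparity-gradient orientation from a
   windowed cross-correlation disparity map; σ_cue = 6 arcmin), each
   quantized into 64 bins. Lookup tables store the conditional circular
   mean of unsigned tilt given the cue triplet,
   `τ̂_u = arg Σ exp(jτ_u)`, and the sign of the conditional mean of
   signed tilt given the quantized signed disparity cue; the local
   estimate is `τ̂_local = τ̂_u · sgn(τ̂_s)`.
2. **Global stage** — local estimates are pooled by a weighted circular
   mean over a neighborhood centered on the target: a fixed circle, or an
   adaptive ellipse whose area, aspect ratio, and orientation depend on
   the target tilt and are fit to the mean absolute circular tilt
   difference `E[|τ_i − τ_0|]` as a function of spatial offset
   (2D-Gaussian fit of the inverted difference map; ellipse size
   summarized by the equivalent diameter `D = 2√(A/π)`).

The package also provides the surrounding machinery: circular statistics,
viewing geometry (range → tilt, slant, binocular disparity), a synthetic
stereo-scene generator with analytic groundtruth, stimulus-sampling
filters replicating psychophysical patch selection, and evaluation tools
(error-vs-diameter sweeps, bootstrap CIs, per-tilt optimal diameters,
reliability diagnostics, a consensus baseline over observers).

## Worked example

```r
library(tiltpool)

geom  <- ViewingGeometry(pixelScale = 2, imageSize = c(128, 128),
                         fixationDistance = 10)
scene <- generateScene(sceneRecipe(seed = 1), geom)
scene
#> RangeScene: 128 x 128 px (4.27 x 4.27 deg)
#>   range: 8.25 - 8.78 m; 16384 valid px
#>   groundtruth tilt: present; half-occlusion mask: present

cues <- computeCueMaps(scene)          # disparity + 3 orientation cues
train <- lapply(2:3, function(s) {
  sc <- generateScene(sceneRecipe(seed = s), geom)
  list(cues = computeCueMaps(sc), tilt = groundtruth(sc))
})
lut <- trainLookup(train, nBins = 16)  # 16 bins/axis at this sample size
lut
#> TiltLookup: 16^3 unsigned cells (3568 occupied, 87.11%), 16 sign cells, method 'printed'
#>   training samples: unsigned 17422, signed 17422

est <- estimateLocal(cues, lut)
gt  <- tiltSigned(groundtruth(scene))
ok  <- est$defined & !is.na(gt)
mean(circAbsDiff(est$tilt[ok] %% 180, gt[ok] %% 180, 180))
#> [1] 40.1    # unsigned error, deg; chance is 45
```

The unsigned error is below the 45° chance level: the cue→tilt tables
carry real signal on held-out scenes. (On this synthetic ensemble the
*sign* stage is only weakly constrained — within-facet disparity gradients
at 5–50 m are comparable to the disparity estimator's sub-pixel noise — so
signed errors sit near chance; see the methods vignette.)

Stage 2, on a patchwise-constant tilt field with noisy local estimates,
shows the pooling tradeoff (averaging out noise vs blurring across real
tilt changes):

```r
geo4 <- ViewingGeometry(4, c(160, 160), fixationDistance = 10)
sc2  <- generateScene(sceneRecipe(anisotropyRule = "isotropic", seed = 5,
                                  correlationLengthMajor = 60,
                                  correlationLengthMinor = 60),
                      geo4, render = FALSE)
gt2 <- tiltSigned(groundtruth(sc2))
set.seed(1)
loc <- (gt2 + rnorm(length(gt2), sd = 40)) %% 360; dim(loc) <- dim(gt2)
tg  <- data.frame(scene = 1, row = sample(30:130, 200, TRUE),
                  col = sample(30:130, 200, TRUE))
tg$reference <- gt2[cbind(tg$row, tg$col)]
sweepDiameters(list(loc), geo4, tg, c(0, 16, 32, 64, 128))[, 1:2]
#>   diameter meanError
#> 1        0      30.0      # the local model (no pooling)
#> 2       16      13.9      # pooling pays ...
#> 3       32      14.2
#> 4       64      24.5
#> 5      128      46.1      # ... until it blurs across tilt changes
```

Error dips at an interior diameter and rises once the region outgrows the
scale of tilt coherence. `meanDiffMapByTilt()` + `fitPoolingEllipse()` +
`poolingSpecFromStats()` fit the adaptive elliptical pooling rules from
scene statistics, and `estimateGlobal(mode = "adaptive")` applies them;
on tilt-dependent anisotropic ensembles the adaptive model beats the fixed
circle at matched equivalent diameter.

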