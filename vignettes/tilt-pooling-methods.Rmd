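---
title: "Hierarchical surface-tilt estimation: models, statistics, and design choices"
author: "tiltpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical surface-tilt estimation: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tiltpool)
```

## The estimation problem

Surface orientation in a 3D scene is parameterized by *slant* (how far a
surface is rotated out of the frontoparallel plane, 0–90°) and *tilt* (the
direction of that rotation: the angle of the surface normal projected into
the frontoparallel plane, measured from the x-axis). Signed tilt lives on
[0°, 360°), unsigned tilt — tilt magnitude irrespective of near/far sign —
on [0°, 180°). Groundtruth tilt is operationalized as the orientation of
the range gradient: the range map is smoothed with a 2D Gaussian of space
constant σ_tilt = 3 arcmin and tilt is the four-quadrant arctangent
`atan2(∂r/∂y, ∂r/∂x)`, so a receding ground plane has tilt 90°.

`tiltpool` implements a two-stage hierarchical estimator of signed tilt
from stereo images:

1. **Local stage.** Three unsigned image cues are measured at each pixel —
   the orientation of the luminance gradient, the dominant orientation of
   the local amplitude spectrum (texture), and the orientation of the
   gradient of a disparity map obtained by windowed normalized
   cross-correlation of the stereo pair (all with space constant
   σ_cue = 6 arcmin). Each cue is quantized into 64 bins (any bin count is
   supported; tests use 16 to keep tables dense at desk scale). A lookup
   table over cue triplets stores the conditional circular mean of
   unsigned groundtruth tilt; a second, 1D table over the quantized
   *signed* disparity cue stores the sign of the conditional mean of
   signed tilt. The local estimate is the product of magnitude and sign.
   Because the tables store phasor accumulators (Σcos, Σsin, count), the
   conditional means are exact sample statistics and tables trained on
   disjoint scene sets merge exactly.

2. **Global stage.** Local estimates are pooled by a weighted circular
   mean over a spatial neighborhood centered on the target: either a
   *fixed circular* region of one diameter for all tilts, or an *adaptive
   elliptical* region whose area, aspect ratio, and orientation depend on
   the tilt at the target. The elliptical parameters are fit to the
   spatial statistics of tilt: the mean absolute circular tilt difference
   as a function of spatial offset, conditioned on the target tilt, is
   inverted into a similarity surface and fit with a zero-centred
   bivariate Gaussian; the covariance's iso-level ellipses give per-tilt
   aspect ratio and relative area, summarized by the equivalent diameter
   D = 2√(A/π). As the average area changes, the relative pattern is held
   fixed.

## Circular arithmetic conventions

All differences are circular distances, `|arg exp(j(a−b))|`. Two
aggregation rules for sets of absolute differences are implemented and
exposed as an explicit option everywhere they are used: the *phasor* rule
(argument of the summed unit phasors of the absolute differences — the
default) and the plain arithmetic mean. The two agree for concentrated
samples and diverge for dispersed ones; neither is silently substituted
for the other.

For 180°-periodic (unsigned) quantities, the general-purpose `circMean`
uses the standard angle-doubling estimator. The lookup tables default to a
different convention — phasors accumulated at the raw unsigned angle with
the mean folded mod 180 (`method = "printed"`) — with `method =
"doubling"` available as a configuration switch. The printed form is the
default for the estimator pipeline; both are tested.

Degenerate resultants (length below 10⁻⁹ of total weight) are an error in
`circMean`; during pooling they trigger a documented fallback to the
target's own local estimate. Antipodal ties in circular differences break
deterministically to +period/2.

## The synthetic scene generator

The generator stands in for a stereo natural-scene database with
co-registered range maps. Its defaults encode the study conditions and are
not tuned per analysis:

* **Viewing geometry.** Inter-pupillary distance 6.5 cm (typical human);
  no scene point nearer than 3 m (enforced with an error); scene mean
  distances drawn log-uniformly over 5–50 m, matching the stimulus
  distance constraints.
* **Surface structure.** An anisotropic Voronoi mosaic of planar facets.
  Facet tilts are drawn from a 24-bin prior with 60% of its mass in the
  four cardinal bins — qualitatively matching the pronounced cardinal
  peaks of tilt priors measured in real scenes without claiming their
  exact shape. Facet slants are uniform on 30–60°. Facet extents default
  to 60 × 25 arcmin (aspect 2.4), elongated *orthogonal* to each facet's
  tilt (the rule suggested by the conditioned difference maps: for a
  target tilt of 0°, locations above and below are most likely to share
  it). The rule is configurable ("orthogonal", "aligned", "isotropic", a
  fixed angle, and an optional per-tilt size multiplier).
* **Depth continuity.** Facet distances follow a smooth base depth field
  whose log-range gradient is slant-consistent (tan σ_base per radian,
  σ_base ∈ 30–60°), so facet boundaries are creases in a piecewise-smooth
  surface rather than large depth steps. Facets bow gently along their
  tilt direction (range quadratic in the along-tilt coordinate, curvature
  capped so the gradient never reverses): the analytic tilt stays exact
  everywhere while shading varies within facets, which is what makes the
  luminance cue informative, as on real curved surfaces.
* **Rendering.** Texture is band-limited noise (element 3 arcmin, RMS
  contrast 20%) compressed per-facet by 1/cos(slant) along the tilt
  direction, so the texture cue is informative; Lambertian shading under a
  fixed directional light. The right image is the left warped horizontally
  by the groundtruth disparity map with cubic-spline sub-pixel
  interpolation; fold-over pixels are recorded as half-occluded, and
  independent Gaussian pixel noise (1% of mean luminance) is added.

What the generator does **not** emulate: photorealistic materials, cast
shadows, specularity, vertical disparity, sensor noise statistics of a
LIDAR range device, and object-level occlusion structure beyond fold-over.
Passing tests on these scenes therefore demonstrate the correctness and
internal consistency of the machinery and the qualitative phenomena
(cardinal priors, anisotropic similarity neighborhoods, the
pooling-diameter tradeoff), not quantitative error levels on real scenes.

A known consequence at desk scale: on these synthetic ensembles the
*signed* disparity cue is only weakly informative — the within-facet
disparity gradient at 5–50 m is comparable to the disparity estimator's
sub-pixel noise — so the sign stage of the image pipeline is only modestly
above chance, and the signed scene error of the image-trained local model
is close to the 90° chance level even when its unsigned error is far below
the 45° chance level. The noiseless identifiability of the lookup-table
machinery itself is established separately with constructed cue-tilt
mappings.

## Numerical choices

* **Gaussian-derivative kernels** are truncated at 3σ and the derivative
  kernel is renormalized so its first moment is exactly −1: gradients of
  affine rasters are exact regardless of how σ falls on the pixel grid.
  A border margin of one kernel radius is marked undefined, never padded.
* **Disparity search range** is derived from the scene's distance bounds
  plus a 2 px margin; the sub-pixel peak is a 3-point quadratic, snapped
  to the integer when the correlation peak is exactly 1 (a parabola
  through the neighbors of a perfect peak would otherwise bias the apex);
  left↔right consistency disagreements above 1 px are flagged
  half-occluded; windows with variance below 10⁻¹⁰ are undefined.
* **Texture cue**: Gaussian-windowed power-of-two patch, amplitude
  spectrum with DC removed, orientation of the major principal axis of the
  spectrum's second-moment matrix, mapped so a grating varying along x
  reads 0°. Patches whose principal-axis ratio is below 1.05 are
  undefined (isotropy guard). This convention is applied identically in
  training and testing.
* **Ellipse fits**: the similarity surface (max − difference) is
  normalized to unit volume and fit by least squares with the precision
  matrix Cholesky-parameterized (positive definite by construction),
  initialized from second moments. The reference level set for "area" is
  the 1-σ ellipse, A = π√det Σ — only relative areas matter downstream,
  so the choice is harmless but is applied consistently. The average
  area across bins uses the arithmetic mean.
* **Empty lookup cells** back off to the marginal conditional mean over
  the unsigned disparity cue alone, then to the global prior mean, with
  per-pixel provenance recorded. A sign cell with an exactly degenerate
  resultant yields +1 with a warning.
* **Pooling membership** is a center-in-ellipse test with equal weights
  (a Gaussian taper exists but is off by default); estimate-keyed
  adaptive pooling keys on the initial local estimate in a single pass,
  with no iteration.
* **Ties** in best-diameter searches break toward the smallest diameter
  (conservative pooling). Correlations between diameter vectors are
  Pearson, with permutation p-values (seeded).

## Design decisions that were genuinely open

* The orientation of the adaptive ellipse can be read two ways from the
  scene statistics ("aligned with the target tilt's orientation" vs
  "elongated orthogonal to the tilt direction"). The rule is an explicit
  parameter of `poolingSpecFromStats()` ("orthogonal", "aligned",
  "fitted"); the default is orthogonal elongation, which is what the
  conditioned difference maps of the generator (and of real scenes)
  show.
* Whether adaptive pooling keys on groundtruth tilt (oracle analyses) or
  on the local estimate at the target is an analysis choice; both are
  first-class (`keyMode`).
* The factored local model (unsigned magnitude from three cues × sign
  from the signed disparity cue) is the only implemented form; a joint
  signed posterior over all three cues is deliberately out of scope.
* RMS contrast is defined as 100·sd/mean with the population standard
  deviation, uniform weighting over the aperture; the pipeline is linear
  throughout (no display gamma).
* Lookup tables serialize to a plain JSON format (`writeLookup` /
  `readLookup`) with accumulators at full precision; rasters serialize as
  32-bit float TIFFs normalized to [0, 1] with per-raster offset/scale
  recorded in the JSON sidecar, since that storage range is what the TIFF
  float path defines.

## Problem sizes used in the shipped analyses

The package's own analyses (tests and the acceptance script) run at desk
scale, chosen so each analysis is statistically stable: 128²-pixel
rendered scenes at 2 arcmin/px for the image pipeline; 160–512² range-only
scenes at 4 arcmin/px for the spatial statistics; 20 training scenes for
the pooling-specification fits; 40 evaluation scenes with 100 balanced
targets per tilt bin for the adaptive-vs-fixed comparison; 1000 random
instances for the circular-mean oracle; 10⁵ pairs for the uniform-tilt
identity. The lookup tables in scene-trained analyses use 16 bins per cue
axis so cells stay densely populated at these sample sizes; the 64-bin
tables of the full-scale design are supported and tested with constructed
mappings.

## Known limitations

* The adaptive-vs-fixed advantage at matched equivalent diameter is a few
  degrees under these study conditions; with small evaluation ensembles
  individual off-cardinal tilt bins can fall within sampling noise of
  zero — the per-bin fits of relative area are the limiting factor, as
  they are estimated from far fewer samples than cardinal bins.
* Pooling is not depth-boundary aware: local estimates are averaged
  across facet creases and occlusions. This is by design — gating pooling
  at depth boundaries is explicitly out of scope.
* The reliability diagnostic reports a shift-invariance score for the
  conditionals p(groundtruth | estimate); it does not assert invariance.
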