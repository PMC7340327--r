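Package: tiltpool
Title: Hierarchical Surface-Tilt Estimation with Adaptive Spatial Pooling
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage hierarchical estimation of 3D surface tilt from
    stereo images and co-registered range maps. Stage one estimates signed
    tilt at each pixel from quantized local image cues (luminance, texture,
    and disparity orientation gradients) via lookup tables of conditional
    circular means; stage two pools local estimates over fixed circular or
    adaptive elliptical spatial neighborhoods whose size, aspect ratio, and
    orientation are fit to the spatial statistics of tilt. Includes circular
    statistics, viewing geometry (range to tilt, slant, and binocular
    disparity), a windowed cross-correlation disparity estimator, synthetic
    stereo-scene generation with analytic groundtruth, stimulus-sampling
    filters, and evaluation machinery (error curves over pooling diameter,
    bootstrap confidence intervals, per-tilt optimal diameters, and
    reliability diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'circstats.R'
    'geometry.R'
    'io.R'
    'synthetic.R'
    'cues.R'
    'local_model.R'
    'scene_stats.R'
    'pooling.R'
    'sampling.R'
    'evaluation.R'
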