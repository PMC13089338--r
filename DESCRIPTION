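Package: mesoquant
Title: Quantitative Imaging of Mesoglea Biogenesis and Aboral-Valve Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis toolkit for cnidarian body-column morphometrics
    during the larva-to-polyp transition: bounding-box shape metrics and
    solid-of-revolution volumes from segmented masks, morphospace trajectories
    with abrupt-leakage (volume drop) onset detection, polyline straightening
    of the mesoglea with full-width-at-half-maximum thickness and intensity
    profiling, extracellular-to-intracellular signal ratios, skeleton-based
    elongation scoring of photoconverted tissue patches, and pore-centred
    aboral intensity profiles with depletion-zone width estimation. Includes
    a seeded synthetic-scene generator with analytic ground truth so every
    estimator has a parameter-recovery test, plus exact and approximate
    Wilcoxon rank-sum group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    pracma,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-geometry.R'
    'io.R'
    'scenes.R'
    'morphometry.R'
    'wilcoxon.R'
    'straighten.R'
    'patch.R'
    'aboral.R'
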