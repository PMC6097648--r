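Package: jonquant
Title: Quantification of Gap-Junction Plaques, Active Zones and Dye
    Coupling in Confocal Stacks of the Drosophila Giant-Fiber Circuit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for quantifying 3D confocal image stacks
    of the Drosophila Johnston's Organ to giant-fiber (GF) circuit:
    grayscale top-hat removal of labelling agglomerations, pooled
    stack-histogram auto-thresholding (Intermodes, IsoData, Renyi
    entropy), binary volumetry of synaptic marker overlap (putative
    active zones), a single-pixel-outline dendritic surface-area proxy,
    medial/core dendrite partitioning, Neurobiotin dye-coupling
    cross-sectional area, and per-region ShakB/Brp colocalization.
    Includes a synthetic confocal phantom generator with ground truth so
    the full pipeline and its ANOVA/Tukey group statistics can be
    exercised and validated without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBiology, Neuroscience, Visualization
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'stack-io.R'
    'morph-filter.R'
    'autothreshold.R'
    'quantify.R'
    'phantom.R'
    'group-study.R'
    'stats-report.R'
    'pipeline.R'
    'jonquant-package.R'
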