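Package: macuMap
Title: Deviation-Map and ETDRS Grid Analysis of Macular Layer Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Point-wise deviation-map analysis (MA) of macular retinal-layer
    thickness between study groups, referenced to a control cohort's
    2.5th-97.5th percentile interval, with point-wise Student's t and Tukey
    HSD significance testing, anatomy-oriented partitioning of significant
    areas by the ETDRS grid, and coverage-thresholded measurement of the
    significant fractions per grid cell. The conventional per-cell grid
    analysis (GA) is provided alongside for comparison. Includes a synthetic
    retinal-cohort simulator (layer-specific foveal-pit profiles, spatially
    correlated noise, configurable planted lesions) so the complete pipeline
    is testable without patient data, plus a plain-text thickness exchange
    format, report writers and figure rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'lattice.R'
    'thickness-map.R'
    'cohort.R'
    'etdrs.R'
    'io.R'
    'reference.R'
    'testing.R'
    'measure.R'
    'grid-analysis.R'
    'synthetic.R'
    'plots.R'
    'run-analysis.R'
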