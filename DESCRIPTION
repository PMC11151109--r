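Package: dtcmorph
Title: Quantitative Morphometrics for the C. elegans Distal Tip Cell
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Headless, scriptable pipeline for quantifying the complex and
    variable morphology of the C. elegans hermaphrodite distal tip cell (DTC)
    from confocal Z-stacks. Provides dynamic-range-robust image optimization
    (maximum projection, darkest-pixel background subtraction, gamma contrast
    adjustment), curve-guided straightening to a uniform fixed-box geometry
    with the distal end at left, coordinate-referenced morphological feature
    markup with tab-delimited measurement tables, Sholl intersection
    profiling of binarized cell images, and a calibrated synthetic-image
    generator with full ground truth for validation. All stages are
    deterministic and batch-scriptable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dtcmorph-package.R'
    'utils.R'
    'io.R'
    'markup.R'
    'optimize.R'
    'straighten.R'
    'synth.R'
    'sholl.R'
    'pipeline.R'
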