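Package: sproutlab
Title: Quantitative Image and Track Analysis for Sprouting Angiogenesis Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for endothelial sprouting assays:
    standard-deviation-filter segmentation of spheroid brightfield
    time-lapse with tip-cell distance and invasion-area kinetics,
    reduction of 3D traction-force-microscopy displacement fields around
    sprouts to near-surface means and signed base-to-tip line scans,
    tip-cell solidity and membrane/cytosol intensity ratios, and
    drift-diffusion decomposition of cell migration trajectories with
    mean-square-displacement analysis. Includes seeded synthetic-data
    generators with programmed ground truth so that every stage can be
    validated without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    stats,
    utils,
    grDevices,
    xml2,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
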