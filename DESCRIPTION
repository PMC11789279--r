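Package: spinecyto
Title: Spatial Periodicity and Signalling-Protrusion Morphometry for
    Neuroepithelial Tissue
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of signalling protrusions (cytonemes)
    and spatially periodic gene-expression patterns in pseudostratified
    neuroepithelia such as the embryonic mouse spinal cord. Implements the
    dorsoventral spatial-period pipeline for fluorescence images (region
    extraction, Gaussian blurring, row-mean intensity profiles, polynomial
    detrending, periodogram with Fisher g-test, and autocorrelation
    peak-spacing with a permutation-bootstrap significance envelope),
    morphometry and time-lapse dynamics of traced filopodial protrusions
    (lengths, apicobasal angles, densities, lifetimes, ligand puncta
    counts), an idealised radial-glia packing model of required protrusion
    reach, and seeded synthetic-data generators with full ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    graphics,
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, CellBiology, Spatial, Visualization
RoxygenNote: 7.3.3
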