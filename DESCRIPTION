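Package: sxreduce
Title: Lossy Data Reduction and Merging-Quality Metrics for Serial
    Crystallography Frame Stacks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reducing the data volume of serial crystallography
    (SX/SFX) detector-frame stacks while tracking the information cost.
    Implements the common lossy operators (non-hit vetoing, pixel binning
    with Bragg-peak coordinate remapping, peak-only retention, uniform
    quantization, ADU-to-photon conversion, most-significant-bit rounding
    and an 8-bit minifloat remapping), lossless-codec compression-ratio
    accounting on a chunked stack container, and the split-half merging
    statistics (R_split, CC1/2, CC*, CC_ano, I/sigma, completeness) used
    to judge information loss. A synthetic diffraction-data generator
    produces frames with smooth radial background, Poisson photon noise,
    sparse Gaussian Bragg peaks and integrating-detector gain/offset/readout
    effects, so every operator and metric is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, DataImport, Preprocessing, QualityControl
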