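Package: chondrostage
Title: Image-Based Staging of Chondrocyte Dedifferentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-based evaluation system for the degree of chondrocyte
    dedifferentiation during monolayer expansion. Quantifies per-cell
    fluorescence biomarkers (RBP4, SOD3, IFITM3, F-actin) together with cell
    and nucleus size from multi-channel confocal images, assembles the
    measurements into a rounds-by-sample feature matrix normalized to
    integers in [0, 14000], and assigns unknown chondrocyte samples to
    early or late dedifferentiation stages by projection onto a staged
    (P0/P2/P4/P8) reference model via Euclidean distance and PCA. Also
    implements single-cell QC filters and a five-class pseudotime
    expression-pattern classifier, plus a synthetic-data generator that
    emulates the biphasic dedifferentiation model for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    pheatmap,
    splines,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
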