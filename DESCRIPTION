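Package: vermicelli
Title: Quantifying Cohesin Vermicelli Phenotypes in Images, FRAP Traces
    and Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the chromatin phenotypes produced by
    excess chromatin-bound cohesin ("vermicelli"): nuclear image
    heterogeneity via a two-Gaussian intensity-box decomposition, bead
    detection and inter-bead spacing along fibers, Pearson
    colocalization, cluster segmentation and line profiles; FRAP and
    iFRAP trace normalization with double-exponential residence-time
    fitting; intensity-weighted radius of gyration of 3D connected
    components; and Hi-C contact-matrix statistics including iterative
    correction (ICE) balancing, contact probability P(s), A/B
    compartment eigenvector analysis, compartment switching and mixing
    ratio, saddle enrichment, insulation-score TAD calling, TAD score
    and aggregate TAD analysis. Includes synthetic-data generators with
    known ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    tiff,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
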