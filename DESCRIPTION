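Package: myelinquant
Title: Label-Free Quantification of Gray-Matter Myelin Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying myelin degradation in ex vivo brain tissue
    from label-free optical imaging. Implements relative-retardance slope
    estimation from two-channel polarization-sensitive optical coherence
    tomography (PS-OCT) volumes with tile stitching and ROI averaging; blinded
    randomized grid sub-sampling of annotation regions; multi-annotator myelin
    defect consensus by intersection-over-union matching with z-plane tolerance
    and majority voting; DAB chromogen percent-area quantification by stain
    unmixing; and covariate-controlled linear mixed-effects group statistics
    with Bonferroni pairwise correction. A synthetic-data module generates
    every pipeline input (birefringence-microscopy z-stacks, PS-OCT volumes,
    annotator behaviour, stained sections, confounded cohorts) with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    mgcv,
    lme4,
    lmerTest,
    emmeans,
    withr
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
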