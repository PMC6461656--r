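Package: angioQuant
Title: Quantification of Wound-Healing Angiogenesis from Intravital Two-Photon Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying arterial neo-angiogenesis in longitudinal
    intravital two-photon imaging of ear-wound healing. Provides a synthetic-data
    generator emulating a transsected-artery wound cohort (sprout birth and
    elongation, artery-vein anastomoses, tracer perfusion, endothelial calcium
    transients, anti-angiogenic treatment effects), rendering of two-channel
    image series and ROI traces, bolus arrival-time estimation with censoring,
    anastomosis and perfusion classification, sprout segmentation and
    morphometry, calcium transient detection, and the longitudinal mixed-model
    statistics (Poisson GLMM, LMM, treatment-by-time interaction models,
    through-origin perfused-fraction regression, Holm-corrected post-hoc tests,
    Fisher/Wilcoxon/Mann-Whitney tests) used to summarise such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    lme4,
    igraph,
    jsonlite,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
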