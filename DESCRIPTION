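Package: leafspace
Title: Leaf Airspace Morphometry and Stomatal Conductance Analysis from MicroCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies leaf intercellular airspace from X-ray computed
    microtomography image stacks and links it to stomatal anatomy and gas
    exchange. Provides seeded synthetic leaf phantoms with exact ground
    truth, global histogram thresholding (IsoData and minimum algorithms),
    leaf/tissue/airspace mask algebra, porosity depth profiles, triangulated
    iso-surface estimation of exposed mesophyll surface area, sub-stomatal
    cavity detection and stoma matching, the anatomical maximum stomatal
    conductance model, instantaneous water-use efficiency, and a native
    statistical battery (Pearson correlation, one-way ANOVA, Tukey HSD with
    compact letter display), orchestrated by a reproducible sample/cohort
    pipeline with CSV and TIFF outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
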