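Package: coolbat
Title: Water-Fat MRI Cooling-Reheating Analysis of Brown Adipose Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for chemical-shift-encoded
    water-fat MRI studies of cold-induced brown adipose tissue (BAT)
    activity. Provides a digital neck phantom and cohort simulator for
    multi-echo gradient-echo acquisitions, multi-scale regularized
    water-fat separation with decoupled R2* estimation (proton-density
    fat-fraction and R2* mapping), threshold-and-erosion refinement of
    cervical-supraclavicular (sBAT) volumes of interest, automatic
    posterior subcutaneous adipose tissue (SAT) segmentation, rigid
    registration for VOI transfer across scans, exact Wilcoxon
    signed-rank cohort statistics, and a rule that attributes
    cold-induced fat-fraction changes to lipid consumption or perfusion
    from their persistence after reheating.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
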