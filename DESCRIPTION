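Package: csfmetals
Title: Multi-View Association Analysis of CSF Alzheimer Biomarkers and
    Macro- and Microelements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how cerebrospinal-fluid (CSF) biomarkers of
    Alzheimer's disease relate to macro- and microelement concentrations
    measured in CSF and plasma.  Provides a seed-reproducible synthetic
    multi-view cohort generator with planted structure, a Bonferroni-gated
    pairwise correlation screen with confounder-adjusted re-testing, principal
    component analysis with varimax rotation, sampling-adequacy diagnostics and
    factor-score regressions, and a multi-view redescription miner that
    discovers patient subgroups jointly described by AND-only interval rules
    over biomarker and element views, filtered by support bounds, Jaccard
    accuracy and an exact random-subset significance model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
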