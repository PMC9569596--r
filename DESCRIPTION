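Package: lipidpanel
Title: Targeted Lipid-Panel Analysis for Two-Group Liver Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for targeted complex-lipid panels of the kind
    produced by flow-injection MRM lipidomics services: parsing of shorthand
    lipid species names into class and acyl-chain identities, internal-standard
    quantification, lipid class and category concentrations, mol% compositions,
    per-class and total fatty-acid profiles, surrogate desaturase/elongase
    activity indices (SCD1, ELOVL3/5/6, FADS1/2), n-6/n-3 ratio, n-3 index and
    class-ratio biomarkers (TG/DG, PC/PE), and two-group differential abundance
    by Welch's t-test. Ships a synthetic panel generator calibrated to a
    published hepatic lipidome of a mouse model of impaired lipophagy, so the
    whole pipeline is testable without access to raw vendor exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
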