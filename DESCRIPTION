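Package: iequant
Title: Ionization-Efficiency-Based Quantification for Nontarget LC-HRMS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts electrospray ionization efficiency (log IE) of
    chemicals from structural fingerprints and eluent descriptors using
    gradient-boosted regression trees, converts predicted ionization
    efficiencies into instrument-specific response factors through a
    calibrant regression, and estimates molar concentrations of LC-HRMS
    features that lack analytical standards. Fingerprints are computed
    from SMILES for identified compounds or supplied as probability
    tables predicted from MS2 spectra for unidentified features. Includes
    the three-stage descriptor filtering cascade, compound-disjoint model
    validation with y-randomization, a fold-error evaluation suite, and a
    synthetic-data generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
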