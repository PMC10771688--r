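Package: pssnet
Title: Prescriber Patient-Sharing Networks and the Diffusion of Prescribed Safer Supply
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how prescribing innovations spread through
    patient-sharing networks of physicians and nurse practitioners, motivated
    by the uptake of prescribed safer supply (PSS) in British Columbia.
    Provides a synthetic health-claims generator with known diffusion
    parameters, substance-use-disorder cohort definition, keyword-based PSS
    case-finding, monthly weighted patient-sharing network construction with
    lagged peer-exposure measures, adoption and discontinuation panel
    assembly, logistic generalized estimating equations with cluster-robust
    inference, and descriptive reporting with small-cell suppression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    lme4,
    sandwich,
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
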