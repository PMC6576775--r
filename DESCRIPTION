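Package: camoccu
Title: Multi-Scale Occupancy Models for Pooled Camera-Trap Detection Histories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for evaluating camera-trap survey designs with multi-scale
    occupancy models. Per-camera daily detection histories are pooled into
    survey "methods" (subsets of co-located cameras combined by logical OR)
    and analysed with a three-level hierarchical model separating large-scale
    occupancy, daily availability, and method-conditional detection, all on
    the logit scale with optional site- and method-level covariates. Includes
    maximum-likelihood fitting with multi-start quasi-Newton optimization and
    finite-difference standard errors, AICc-based model ranking, Akaike-weight
    model averaging, a staged model-selection workflow, and a hierarchical
    Bernoulli simulator of camera-array data (with missing visits and
    covariates) for design evaluation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
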