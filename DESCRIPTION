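Package: eoa
Title: Ensemble Outcome Agreement Index for Multi-Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the Ensemble Outcome Agreement (EOA) index, a [0,1]
    confidence measure that a multi-model ensemble outcome fulfils a
    threshold hypothesis, built from exhaustive (or sampled) enumeration of
    all sub-ensemble aggregates. Includes the adaptation-value and
    recovery-value response metrics used in climate-impact adaptation
    studies, assembly of impact/adaptation response surfaces and EOA
    surfaces over joint temperature-precipitation perturbation grids, a
    recommendation filter on EOA classes, and a synthetic multi-model run
    generator with analytically known agreement structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
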