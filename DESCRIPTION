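Package: camkatria
Title: CaMKII Overexpression and Oxidation in a Mouse Atrial Myocyte Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-cell mouse atrial electrophysiology and calcium-cycling
    simulator coupled to an eight-state Markov chain of CaMKII activation and
    oxidation. Provides a six-fold CaMKII-overexpression remodeling recipe,
    pacing and burst protocols with delayed-afterdepolarization detection,
    ion and phosphorylation clamps, and ryanodine-receptor activation
    threshold / release-amplitude mapping over the SR-calcium by
    RyR-phosphorylation plane.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: deSolve, minpack.lm, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
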