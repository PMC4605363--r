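Package: seesawleak
Title: Leak Kinetics Evaluation for Seesaw DNA Strand Displacement Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate and reduce leaky reactions in toehold-mediated
    DNA strand displacement with seesaw gates. Provides a domain-level strand
    toolkit (assembly of oligonucleotides from domain formulas, validation
    against printed sequences, duplex mapping, hairpin reporter geometry),
    three empirical exponential leak models (reaction time by input multiple,
    fuel-strand concentration, magnesium concentration) with exact derivative
    and asymptotic analysis, nonlinear least-squares fitting with parameter
    recovery diagnostics, a synthetic fluorescence time-series generator with
    additive noise, a mass-action seesaw simulator with an explicit leak
    pathway, and reaction-condition recommendation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
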