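Package: quenchkin
Title: Enzyme Inhibition Kinetics, Fluorescence Quenching and Binding
    Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the in vitro characterisation of
    reversible enzyme inhibitors, built around the xanthine oxidase /
    polyphenol assay family. Extracts initial rates from UV progress
    curves, fits IC50 dose-response curves, tests reversibility from
    velocity-versus-enzyme lines, estimates mixed-inhibition constants
    (Ki, Kis) by Lineweaver-Burk secondary plots with a direct nonlinear
    cross-check, analyses fluorescence quenching titrations (inner-filter
    correction, Stern-Volmer Ksv/Kq, double-log Ka and binding-site number
    n, static/dynamic classification), and derives binding thermodynamics
    (van't Hoff dH, dS; Gibbs dG; driving-force classification). A seeded
    forward simulator generates every input table the analysis stages
    consume, enabling exact round-trip parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
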