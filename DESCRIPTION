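Package: ivfcea
Title: Cost-Effectiveness Microsimulation of Multi-Cycle IVF Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level Monte Carlo simulation of assisted-reproduction
    programs of up to three IVF cycles (fresh and frozen embryo transfer,
    with ICSI as an optional fertilization technique), built to compare
    ovarian-stimulation strategies in PCOS patients on three outcomes:
    mean cost per procedure, ongoing-pregnancy rate at 12 gestational
    weeks, and cost per pregnancy. Stage transition probabilities and
    unit costs are specified as uniform min-max ranges and redrawn at
    every use, giving a probabilistic sensitivity analysis. Includes an
    exact closed-form expected-value oracle over the decision tree, a
    scenario generator for testing and one-way sensitivity scans, and a
    command-line interface with JSON/CSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
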