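Package: genodiet
Title: Genotype-Informed Weight-Loss Trial Design, Simulation, and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing, simulating, and analysing randomized
    weight-loss trials in which participants are classified a priori as
    fat-responders or carbohydrate-responders from a panel of diet-response
    SNPs read out of direct-to-consumer genotype exports. Includes parsers
    for 23andMe- and AncestryDNA-style raw files, a config-driven genetic
    risk score with four-way responder classification, stratified permuted-
    block randomization with BMI balancing, Mifflin-St Jeor energy
    prescription, baseline-adjusted treatment-effect estimation with
    Holm-Bonferroni adjustment, HOMA-IR association models, closed-form and
    simulation-based power, and a seeded synthetic-data generator that
    emulates the full trial so every stage can be exercised end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
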