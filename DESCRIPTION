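Package: griprepair
Title: Biomechanically Calculated Incisional Hernia Repair Planning and
    Registry Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biomechanically calculated reconstruction (BCR) of
    complex incisional hernias. Computes the critical resistance to impacts
    related to pressure (CRIP) required of a repair, the gained resistance
    (GRIP) achieved by a mesh plan via the mesh-defect area ratio (MDAR) and
    material, position, fixation and closure coefficients, and iterates mesh
    sizing and fixation until GRIP exceeds CRIP. Includes a clinical
    complexity score for incisional hernia repair, an abdominal-wall
    instability map stage operating on rest-to-Valsalva displacement fields,
    a seeded generator of stratified synthetic registry cohorts, and the
    nonparametric outcome-statistics stage (stratum descriptives,
    Kruskal-Wallis with pairwise Mann-Whitney follow-ups, contingency rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
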