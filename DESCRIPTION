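Package: morphodyn
Title: Microglia Morphodynamics: Sholl Morphometrics, Surveillance,
    Saltatory Migration and Phagocytosis Gating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for microglial morphology and
    behaviour from live and fixed imaging experiments. Reads SWC
    skeleton reconstructions and computes 3D Sholl profiles, total
    process length, tips and branch points; implements the time-lapse
    surveillance statistic (Huang minimal-fuzziness thresholding,
    frame-pair symmetric difference, scanned area per time window);
    decomposes saltatory soma-migration tracks into idling and active
    phases from instantaneous speeds and mean squared displacement;
    measures lesion-directed process-extension speeds; gates
    flow-cytometry-style phagocytosis event tables; and provides the
    accompanying statistical toolkit (normality-gated test choice,
    exact Mann-Whitney U, Holm adjustment, Fisher's exact test,
    2^-ddCt fold changes). Includes synthetic-data generators with
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
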