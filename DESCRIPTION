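Package: bbbalert
Title: Explainable Blood-Brain-Barrier Penetration Classification and
    Substructure Alert Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates labelled SMILES tables of blood-brain-barrier (BBB)
    penetration data, featurizes molecules with folded extended-connectivity
    (circular) fingerprints that keep a per-bit atom-environment registry,
    trains tree-ensemble penetration classifiers with randomized
    hyperparameter search and (nested) cross-validation, explains individual
    predictions with a perturbation-based local linear surrogate over the
    binary fingerprint features, and aggregates the per-bit explanation
    weights into a ranked table of molecular substructures ("alerts") that
    drive predicted penetration. Includes a seeded synthetic molecule-library
    generator with planted alert substructures so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
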