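Package: kvarann
Title: Functional Classification of Potassium Channel Variants from
    Structural and Evolutionary Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether single amino-acid variants of the cardiac
    potassium channel KCNQ1 (Kv7.1) disrupt four electrophysiological
    parameters (peak current density, voltage of half-maximal activation,
    activation and deactivation time constants). Computes residue
    microenvironment descriptors from a membrane-oriented 3-D structure
    (functional density, neighbor vector, pore-axis distance, membrane
    burial, physicochemical substitution deltas) and PSSM-derived
    evolutionary substitution scores, trains multitask feed-forward
    neural networks under 25-fold cross-validation with class
    oversampling, and evaluates them with Matthews correlation, ROC/AUC,
    entropy separation and a consistency-based input-sensitivity
    analysis. Includes a synthetic-fixture generator (idealized helix
    bundles, tunable-conservation PSSMs, planted-rule variant datasets)
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
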