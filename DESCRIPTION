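Package: shortcutaudit
Title: Shortcut-Learning Audits for Radiograph Classifiers on Confounded Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to audit convolutional image classifiers for shortcut
    learning, the exploitation of source-specific confounds (laterality-marker
    styles, border radiopacity, patient positioning) instead of genuine
    pathology. Generates two-source confounded radiograph-like synthetic
    datasets with planted spurious features and a genuine diffuse lung-opacity
    signal; trains small multi-label convolutional classifiers with SGD and
    validation-AUROC epoch selection; quantifies internal-versus-external
    generalization gaps; attributes predictions to pixels with Expected
    Gradients and Integrated Gradients; trains cycle-consistent adversarial
    translators between class domains for counterfactual difference maps and
    classifier-flip rates; and validates candidate shortcuts behaviorally with
    marker-swap and region-relocation tests scored by Monte-Carlo empirical
    p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
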