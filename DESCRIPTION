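Package: deepSRV
Title: Residue-Residue Interaction Prediction from Disentangled Contact
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts inter-chain residue-residue contact counts from
    protein complex structures into a space of adjusted standardized
    residuals, disentangles that space by principal-component
    decomposition into per-component projection scores and re-projected
    residual matrices, and uses the resulting statistics as
    sequence-only features for an extremely randomized tree classifier
    that predicts interacting residue pairs between two protein chains.
    Includes leave-one-complex-out evaluation, ROC and confusion
    metrics, and synthetic-complex generators with planted residue-type
    interaction preferences for end-to-end validation without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    ranger,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
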