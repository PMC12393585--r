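Package: mvecho
Title: Multi-View Echocardiographic Study Embeddings with Adversarial
    Debiasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aggregates variable-size sets of echocardiographic video
    embeddings into fixed-length study-level embeddings with a masked set
    transformer, pretrained by random view masking with auxiliary clinical
    heads and gradient-reversal adversarial demographic debiasing.
    Provides a view-grouped weighted-averaging baseline, a subject-based
    cross-validated linear-probe evaluation harness over binary clinical
    tasks, and a fairness audit (demographic probes, subgroup
    decomposition, adversarial-weight sweeps, mixed-effects comparisons
    with Holm-Bonferroni correction).  A synthetic cohort generator
    emulates the statistical structure of a multi-view echo dataset
    (view-count law, demographic marginals, latent pathophysiology spread
    across view types, calibrated task prevalences, label missingness and
    an injectable demographic shortcut) so the full pipeline runs without
    any protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
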