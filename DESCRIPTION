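Package: tnmstager
Title: Extraction of Prostate Cancer TNM Stage from Free-Text Clinical Notes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patient-level extraction of clinical and pathological TNM
    stage for prostate cancer from free-text clinical notes. Provides a
    rule-based engine (a compact TNM pattern grammar, a curated staging
    lexicon, ConText-style negation/temporality/experiencer handling, and
    longitudinal patient-level resolution with dichotomization), a
    semi-supervised machine-learning arm (count-based skip-gram-style word
    embeddings, keyword-context sentence averaging, per-axis binary support
    vector machines with random hyperparameter search and cross-validation),
    an evaluation and registry-imputation harness (precision/recall/F1,
    Cohen's kappa, no-overwrite imputation accounting), and a seeded
    synthetic note-corpus generator with ground-truth labels for testing
    and benchmarking where institutional data cannot be shared.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
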