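Package: playseq
Title: Behavioral Sequence Analysis of Structured Play Observation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lag-sequential analysis of coded behavior streams from
    structured play observation of autistic and typically developing children.
    Provides event-log preprocessing (merge and minimum-duration rules),
    first-order and multi-step transition probability matrices, sequence
    complexity metrics (bigram Shannon entropy, average sequence length,
    cyclicity and transitivity), frequent behavior-chain mining, coder
    reliability statistics (Cohen's kappa, intraclass correlation),
    physiological-behavioral coupling via moving-average smoothing,
    normalized cross-correlation and event-locked contrasts, Bernoulli-mixture
    latent class analysis with EM estimation, information criteria, adjusted
    and bootstrap likelihood-ratio model selection, and latent-class-stratified
    intervention-response analysis (responder rates, logistic regression,
    covariate-adjusted contrasts, entropy mediation). A seeded synthetic cohort
    generator emulates the statistical structure of the study design so the
    whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
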