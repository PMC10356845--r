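Package: reinstatr
Title: Temporal-Context Reinstatement Analysis of Repeated-Exposure fMRI Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking the re-expression of trial-level fMRI activity
    patterns across repeated image exposures to long-timescale temporal-context
    memory. Implements behavioral scoring for continuous-recognition experiments
    (rank-based temporal error, per-participant permutation chance tests,
    signal-detection summaries), exposure-pair representational similarity with
    cross-run exclusion and Fisher transformation, mixed-effects logistic and
    linear models with log-lag covariates and likelihood-ratio model comparison,
    two image-specificity resampling analyses (shuffled exposure-mapping null
    and session-matched target-versus-foil difference scores), and a synthetic
    experiment generator with planted reinstatement structure for
    parameter-recovery and calibration testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
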