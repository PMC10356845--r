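# Shared configuration for the analysis scripts. Everything downstream is a
# deterministic function of this file.

library(reinstatr)

ANALYSIS_SEED <- 2026L
RESULTS_DIR <- "results"

analysis_config <- function() {
  default_config(
    seed = ANALYSIS_SEED,
    n_permutations = 1000,
    design = design_params(),           # 8 participants, 10 sessions, 150 images
    rois = list(roi_spec("CA1", role = "precision"),
                roi_spec("PHC", role = "confidence"),
                roi_spec("V1", role = "none")),
    truth = truth_params(),
    specificity_rois = "CA1")
}

dir.create(RESULTS_DIR, showWarnings = FALSE)
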