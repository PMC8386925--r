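# Shared configuration for the numbered analysis scripts.
# All stages are pure functions of this scenario, so any script can be
# re-run in isolation and will see exactly the same synthetic study.

library(aadiet)

STUDY_SEED <- 1L   # master seed of the worked study
SCENARIO <- sim_scenario(seed = STUDY_SEED)
RESULTS_DIR <- file.path("results", "study")
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
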