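# Shared settings for the analysis drivers. The synthetic study emulates a
# 16-compound heterocycle cohort: HOMO-LUMO gaps spanning 0.005-0.11 energy
# units, rainbow MEP surface renders, ESP extrema, and IC50s for WI-38
# fibroblasts plus three tumor lines.
library(cdftrank)

STUDY_SEED <- 2026L
N_COMPOUNDS <- 16L
STUDY_DIR <- "scratch/study"     # generated inputs (images are binary)
RESULTS_DIR <- "results"         # analysis tables (text)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
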