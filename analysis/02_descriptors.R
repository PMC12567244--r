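#!/usr/bin/env Rscript
# Conceptual-DFT global reactivity descriptors for the simulated cohort.
# Softness tracks the inverse gap (S = 2/gap); the softest compound is the
# most reactive under the HSAB view, the hardest the most stable.
source("analysis/00_config.R")

energies <- read_compound_energies(file.path(STUDY_DIR, "energies.csv"))
desc <- compute_descriptor_table(energies, convention = "paper")
write.csv(desc, file.path(RESULTS_DIR, "descriptors.csv"), row.names = FALSE)

softest <- desc[which.max(desc$softness), ]
hardest <- desc[which.min(desc$softness), ]
cat("Descriptors for", nrow(desc), "compounds -> results/descriptors.csv\n")
cat(sprintf("Softest:  %s (gap %.4f, S %.2f, omega %.3f)\n",
            softest$compound_id, softest$gap, softest$softness,
            softest$electrophilicity))
cat(sprintf("Hardest:  %s (gap %.4f, S %.2f, omega %.3f)\n",
            hardest$compound_id, hardest$gap, hardest$softness,
            hardest$electrophilicity))
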