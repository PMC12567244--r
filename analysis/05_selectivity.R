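#!/usr/bin/env Rscript
# Selectivity indices: IC50 in WI-38 fibroblasts relative to each tumor
# line; SI > 1 means the compound hits tumor cells at lower dose than
# normal cells, and larger is safer.
source("analysis/00_config.R")

ic50 <- read_ic50_table(file.path(STUDY_DIR, "ic50.csv"))
si <- si_table(ic50, normal_line = "WI-38")
si$si_display <- display_si(si$si)
write.csv(si, file.path(RESULTS_DIR, "si.csv"), row.names = FALSE)

cat("Selectivity indices for", length(unique(si$compound_id)),
    "compounds x", length(unique(si$cell_line)), "tumor lines",
    "-> results/si.csv\n")
top <- si[which.max(si$si), ]
cat(sprintf("Most selective pair: %s on %s (SI %.2f)\n",
            top$compound_id, top$cell_line, top$si_display))
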