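#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-leaf-side study.
#
# One sample per (species, individual, leaf side): 24 species x 3 plants
# x 2 sides = 144 samples, ~14,000 reads each. The lower surface gets a
# smaller migration parameter (m = 0.05 vs 0.15) and stronger host
# filtering; ground truth is exported alongside the data.

library(leafside)

seed <- as.integer(Sys.getenv("LEAFSIDE_SEED", "1"))
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- study_design(seed = seed)
sim <- simulate_study(design)

write_feature_table(sim$table, file.path(out, "feature_table.tsv"))
write_sample_sheet(sim$sheet, file.path(out, "metadata.tsv"))
write_truth_json(sim$truth, file.path(out, "truth.json"))

message(sprintf("simulated %d samples x %d taxa (seed %d)",
                ncol(sim$table), nrow(sim$table), seed))
message(sprintf("planted: m_upper = %.2f, m_lower = %.2f, %d shared ",
                design$m_upper, design$m_lower, design$n_plant_associated),
        "plant-associated taxa, ",
        sprintf("%d endemic taxa per species", design$n_endemic_per_species))
message("wrote ", out, "/{feature_table,metadata}.tsv + truth.json")
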