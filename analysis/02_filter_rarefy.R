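#!/usr/bin/env Rscript
# Stage 2: read filters and rarefaction.
#
# Counts of <= 2 reads in any one sample are zeroed (denoising), then
# samples are rarefied to 4,000 reads for the diversity, neutral-model
# and core analyses. The 0.1% total-relative-abundance pre-filter used
# ahead of differential-abundance testing is applied to the unrarefied
# table for the census it implies.

library(leafside)

seed <- as.integer(Sys.getenv("LEAFSIDE_SEED", "1"))
src <- "results/synthetic"
out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

raw <- read_feature_table(file.path(src, "feature_table.tsv"))
filtered <- filter_low_counts(raw, 2)
rep <- attr(filtered, "filter_report")
message(sprintf("low-count filter: zeroed %d entries, dropped %d taxa",
                rep$entries_zeroed, length(rep$taxa_dropped)))

da <- filter_total_relabund(raw, 0.001)
message(sprintf("0.1%% abundance floor would keep %d of %d taxa",
                nrow(da), nrow(raw)))

rarefied <- rarefy_table(filtered, 4000, seed = seed_stream(seed, 2)[2])
message(sprintf("rarefied to 4,000 reads: %d samples retained",
                ncol(rarefied)))

write_feature_table(filtered, file.path(out, "filtered.tsv"))
write_feature_table(rarefied, file.path(out, "rarefied.tsv"))
message("wrote ", out, "/{filtered,rarefied}.tsv")
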