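#!/usr/bin/env Rscript
# Stage 3 — functional domains and cross-cohort overlap.
#
# Bins every feature into a named functional domain (memory skewing,
# baseline signaling per lineage, cytokine sensitivity per lineage,
# systemic proteins, subset frequencies), intersects the significant
# domains of the three inflammation drivers, and exports the effect sizes
# for the domains shared by all three.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "00_config.R"))

run_pipeline(config, outdir = outdir, stages = "domains")

ov <- read.delim(file.path(outdir, "overlap.tsv"))
cat("unique significant domains:", sum(ov$count), "\n")
print(ov[, c("region", "count")], row.names = FALSE)
shared <- ov$members[ov$region == "age_hiv_hcv"]
cat("shared by all three drivers:", shared, "\n")
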