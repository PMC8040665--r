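#!/usr/bin/env Rscript
# Stage 4 — global signaling clustering.
#
# Hierarchically clusters the HCV-cohort subjects on their 84 z-scored
# baseline signaling nodes, selects the number of clusters by the gap
# statistic (uniform reference, 100 draws), and tests cluster enrichment
# for HCV status by the exact hypergeometric test.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "00_config.R"))

run_pipeline(config, outdir = outdir, stages = "cluster")

gap <- read.delim(file.path(outdir, "gap.tsv"))
enr <- read.delim(file.path(outdir, "cluster_enrichment.tsv"))
cat("gap statistic chose k =", gap$chosen_k[1], "\n")
cat("strongest cluster enrichment:\n")
print(enr[which.min(enr$p), ], row.names = FALSE)
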