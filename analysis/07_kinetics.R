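#!/usr/bin/env Rscript
# Stage 7 — stimulation-response kinetics.
#
# Summarizes the pSTAT1 response to IFN-alpha per lineage across the
# treatment timepoints (mean +/- SEM, plus young-control-referenced
# z-scores), and tests pre vs post by Wilcoxon matched pairs and the
# cross-cohort baseline by Kruskal-Wallis.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "00_config.R"))

run_pipeline(config, outdir = outdir, stages = "kinetics")

traj <- read.delim(file.path(outdir, "trajectories.tsv"))
dc <- traj[traj$cell_type == "DC" & traj$scale == "response", ]
cat("DC pSTAT1-IFNa response trajectory (mean +/- SEM):\n")
print(dc[match(c("pre", "wk1", "wk2", "wk4", "wk8", "wk12", "post"),
               dc$timepoint), c("timepoint", "n", "mean", "sem")],
      row.names = FALSE)
tests <- read.delim(file.path(outdir, "group_tests.tsv"))
paired <- tests[tests$test == "wilcoxon_signed_rank", ]
cat("\npre vs post Wilcoxon matched pairs:\n")
print(paired[, c("cell_type", "p")], row.names = FALSE)
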