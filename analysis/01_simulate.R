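#!/usr/bin/env Rscript
# Stage 1 — synthetic cohorts.
#
# Generates the three cohorts (aging 60+29, HIV 24+45, HCV 14+11), the
# 357-feature immune panel (84 baseline signaling nodes = 12 parameters x 7
# lineages, 168 stimulation responses, 42 subset frequencies, 63 serum
# analytes), cross-sectional measurements with planted driver effects and a
# planted 4-block correlation structure, and the longitudinal HCV treatment
# course (pre, wk1-wk12, post) with decaying viral load, a week-2 DC pulse
# and 13 planted post-treatment improvements.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "00_config.R"))

run_pipeline(config, outdir = outdir, stages = "simulate")

subjects <- read.delim(file.path(outdir, "cross_sectional", "subjects.tsv"))
features <- read.delim(file.path(outdir, "cross_sectional", "features.tsv"))
vl <- read.delim(file.path(outdir, "longitudinal", "viral_load.tsv"))

cat("cohorts:\n")
print(table(subjects$cohort, subjects$group))
cat("panel:", nrow(features), "features;",
    sum(features$modality == "baseline_signaling"), "signaling nodes\n")
cat("viral load drops below detection by week",
    min(vl$week[vl$viral_load <= 15]), "\n")
cat("tables written under", outdir, "\n")
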