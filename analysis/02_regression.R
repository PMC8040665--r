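#!/usr/bin/env Rscript
# Stage 2 — cross-cohort feature selection.
#
# Z-normalizes within each cohort, fits the linear model
# y ~ age + sex + CMV + HIV + HCV per feature, derives coefficient p-values
# from 1000 permutations of each driver column, and selects features at
# Storey q < 0.2 per (cohort, covariate).
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "00_config.R"))

run_pipeline(config, outdir = outdir, stages = "regress")

rr <- read.delim(file.path(outdir, "regression_results.tsv"))
truth <- read.delim(file.path(outdir, "truth.tsv"))
driver_cohort <- c(age = "aging", hiv = "hiv", hcv = "hcv")
for (d in names(driver_cohort)) {
  sub <- rr[rr$covariate == d & rr$cohort == driver_cohort[[d]], ]
  planted <- truth$feature_id[truth$driver == d]
  called <- sub$feature_id[sub$significant]
  cat(sprintf("%-4s driver: %3d significant (q<0.2); sensitivity %.2f, FPR %.3f\n",
              d, length(called), mean(planted %in% called),
              sum(!(called %in% planted)) / (nrow(sub) - length(planted))))
}
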