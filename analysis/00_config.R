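# Shared settings for the numbered analysis drivers. Each driver can be run
# standalone (earlier stages' tables are read from `outdir`), in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_regression.R
#   ...
library(immunosig)

analysis_seed <- 20210402
outdir <- "results/pipeline"
config <- default_config(seed = analysis_seed)
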