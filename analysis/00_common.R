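# Shared setup for the analysis drivers: one fixed study configuration
# (40 synthetic specimens, master seed 20260101) and the run/results layout.
suppressPackageStartupMessages(library(mc3ssm))

study_config <- default_pipeline_config(n_specimens = 40L, seed = 20260101L)
run_dir <- "scratch/study40"
results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
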