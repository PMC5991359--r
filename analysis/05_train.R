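#!/usr/bin/env Rscript
# Train the shape-only, density-only and combined (correlation) PCA models
# and export the variance table.
source(file.path("analysis", "00_common.R"))

models <- run_stage("train", study_config, run_dir)
file.copy(file.path(run_dir, "train", "variance_table.csv"),
          file.path(results_dir, "variance_table.csv"), overwrite = TRUE)
for (fl in names(models)) {
  m <- models[[fl]]
  cat(sprintf("%-9s: %2d components for %.0f%% variance; leading fractions %s\n",
              fl, m$n_retained, 100 * m$variance_target,
              paste(sprintf("%.1f%%", 100 * head(m$variance_fractions, 3)),
                    collapse = " ")))
}
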