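#!/usr/bin/env Rscript
# Leave-one-out reconstruction error of the combined model.
source(file.path("analysis", "00_common.R"))

curve <- run_stage("loo", study_config, run_dir)
file.copy(file.path(run_dir, "loo", "loo_curve.csv"),
          file.path(results_dir, "loo_curve.csv"), overwrite = TRUE)
cat(sprintf("LOO geometric RMS: %.2f mm at k=0 -> %.2f mm at k=%d; density RMS %.3f -> %.3f g/cm^3.\n",
            curve$geometric_rms[1], tail(curve$geometric_rms, 1),
            tail(curve$k, 1), curve$density_rms[1],
            tail(curve$density_rms, 1)))
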