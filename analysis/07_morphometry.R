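#!/usr/bin/env Rscript
# Landmark morphometry of the fitted population and the +/-2 SD effect of
# the leading combined modes.
source(file.path("analysis", "00_common.R"))

out <- run_stage("morpho", study_config, run_dir)
for (f in c("morphometry.csv", "mode_effects.csv", "mode_effects.json"))
  file.copy(file.path(run_dir, "morpho", f), file.path(results_dir, f),
            overwrite = TRUE)
eff1 <- out$effects[[1]]$percent_change
cat(sprintf("Mode 1 at +/-2 SD: total area %+.1f%%, dorsal BMD %+.1f%%, palmar BMD %+.1f%%.\n",
            eff1$pct_change[eff1$metric == "total_area"],
            eff1$pct_change[eff1$metric == "dorsal_condylar_bmd"],
            eff1$pct_change[eff1$metric == "palmar_condylar_bmd"]))
rat <- out$effects[[3]]$area_ratio
cat(sprintf("Mode 3 lateral/medial condylar area ratio: %.3f (-2 SD) -> %.3f (+2 SD).\n",
            rat["minus"], rat["plus"]))
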