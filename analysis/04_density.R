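#!/usr/bin/env Rscript
# Rasterize every specimen into a calibrated CT-like volume and sample the
# subchondral density along inward normals of the fitted meshes.
source(file.path("analysis", "00_common.R"))

run_stage("densify", study_config, run_dir)
dn <- readRDS(file.path(run_dir, "densify", "density.rds"))
cat(sprintf("Sampled %d x %d node densities; %d flagged rays; mean rho_HA %.3f g/cm^3.\n",
            nrow(dn$rho_ha), ncol(dn$rho_ha), sum(dn$flagged),
            mean(dn$rho_ha, na.rm = TRUE)))
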