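#!/usr/bin/env Rscript
# Register the template to every cloud: host-mesh (FFD) coarse fit, then the
# per-node fine fit. The interesting output is the per-specimen RMS.
source(file.path("analysis", "00_common.R"))

run_stage("fit", study_config, run_dir)
fits <- readRDS(file.path(run_dir, "fit", "fits.rds"))
tab <- data.frame(specimen = seq_along(fits$fits),
                  coarse_rms_mm = fits$coarse_rms,
                  fine_rms_mm = vapply(fits$fits, `[[`, 0, "rms"))
write.csv(tab, file.path(results_dir, "fit_rms.csv"), row.names = FALSE)
cat(sprintf("Coarse fit: mean %.3f mm (range %.3f-%.3f); fine fit: mean %.3f mm.\n",
            mean(tab$coarse_rms_mm), min(tab$coarse_rms_mm),
            max(tab$coarse_rms_mm), mean(tab$fine_rms_mm)))
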