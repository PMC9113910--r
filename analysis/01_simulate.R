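#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a clinical follow-up table drawn at
# the study's printed group summaries, and a small imaging cohort (reduced
# 24x24x12 grid, TR 2 s, 260 volumes) with one planted amplitude-elevated
# region, written as NIfTI + CSV under results/data/.

suppressPackageStartupMessages(library(phnalff))
seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

clin <- simulate_clinical(clinical_sim_config(seed = seed))
write_clinical_table(clin, file.path(out, "clinical.csv"))
cat(sprintf("clinical table: %d subjects (%d per group), VAS range %.1f-%.1f\n",
            nrow(clin), nrow(clin) / 2, min(clin$vas_baseline),
            max(clin$vas_baseline)))

cfg <- sim_config()
cohort <- simulate_cohort(cfg, n_per_group = 3L, seed = seed)
write_mask(cohort$mask, file.path(out, "mask.nii.gz"), cfg$voxel_size_mm)
write_atlas(cohort$atlas, file.path(out, "atlas.nii.gz"), cfg$voxel_size_mm)
for (s in cohort$subjects) {
  write_timeseries(s$vol, file.path(out, sprintf("%s_%s_bold.nii.gz",
                                                 s$subject_id, s$group)))
}
cat(sprintf("imaging demo cohort: %d subjects on a %s grid, %d volumes,\n",
            length(cohort$subjects),
            paste(cfg$grid, collapse = "x"), cfg$n_timepoints))
cat(sprintf("planted region: label %d, %d voxels, amplitude multiplier %g\n",
            cfg$planted_regions[[1]]$label, sum(cohort$atlas$data == 1L),
            cfg$planted_regions[[1]]$multiplier))
cat("wrote", out, "\n")
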