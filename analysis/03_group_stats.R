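#!/usr/bin/env Rscript
# Voxel-wise group analysis on a full-size synthetic cohort (n = 20 per
# group): two-sample t on mALFF maps, cluster-extent thresholding at voxel
# p < 0.001 and extent > 36, atlas labelling — and the same pipeline with
# no planted effect as a negative control. Writes the cluster tables.

suppressPackageStartupMessages(library(phnalff))
seed <- 1L
out <- "results/group_stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cat("planted-effect cohort (60-voxel region, amplitude x2)...\n")
rec <- planted_region_recovery(seed)
write_cluster_table(rec$clusters, file.path(out, "clusters_planted.csv"))
print(rec$clusters, row.names = FALSE)
cat(sprintf("recovered planted region: %s (%d increase / %d decrease clusters)\n",
            rec$recovered, rec$n_increase, rec$n_decrease))

cat("\nnull cohort (no planted effect), smoothing off for calibration...\n")
nul <- null_calibration_run(seed, sim_config(grid = c(16L, 16L, 8L)))
cat(sprintf("voxel p<0.05 fraction %.4f over %d voxels (nominal 0.05); %d clusters\n",
            nul$fraction, nul$n_voxels, nul$n_clusters))
write.csv(data.frame(seed = seed, type1_fraction = nul$fraction,
                     n_voxels = nul$n_voxels, n_clusters = nul$n_clusters),
          file.path(out, "null_calibration.csv"), row.names = FALSE)
cat("wrote", out, "\n")
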