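#' End-to-end group pipeline on a simulated or loaded cohort
#'
#' Runs preprocess (discard, detrend, smooth), ALFF/f-ALFF mapping,
#' standardization, the voxel-wise two-sample test
#' (treatment vs control) and cluster-extent thresholding, and labels the
#' clusters with the cohort atlas.
#'
#' @param cohort list with `subjects` (each `list(subject_id, group, vol)`),
#'   `mask`, `atlas` — the shape returned by [simulate_cohort()].
#' @param preproc a [preprocess_config()].
#' @param band,total_band ALFF bands, Hz.
#' @param measure `"alff"` or `"falff"` — which map feeds the group test.
#' @param standardize standardization mode, or "none".
#' @param voxel_p,extent,connectivity cluster thresholding settings.
#' @return list: `t`, `p` maps, `df`, `clusters`, plus `maps` (per-subject
#'   standardized maps by group).
#' @export
run_group_pipeline <- function(cohort, preproc = preprocess_config(),
                               band = c(0.02, 0.07),
                               total_band = c(0, 0.25),
                               measure = c("alff", "falff"),
                               standardize = "divide_by_global_mean",
                               voxel_p = 0.001, extent = 36L,
                               connectivity = 26L) {
  measure <- match.arg(measure)
  maps <- cohort_maps(cohort, preproc, band, total_band)
  sel <- lapply(maps, function(g) lapply(g, `[[`, measure))
  res <- group_compare(sel$treatment, sel$control, cohort$mask,
                       atlas = cohort$atlas, standardize = standardize,
                       test = "two_sample", voxel_p = voxel_p,
                       extent = extent, connectivity = connectivity)
  res$maps <- sel
  res
}

#' Per-subject ALFF and f-ALFF maps for a whole cohort
#' @inheritParams run_group_pipeline
#' @return list with `treatment` and `control`, each a list (one element
#'   per subject) of `list(alff =, falff =)` maps.
#' @export
cohort_maps <- function(cohort, preproc = preprocess_config(),
                        band = c(0.02, 0.07), total_band = c(0, 0.25)) {
  out <- list(treatment = list(), control = list())
  for (s in cohort$subjects) {
    pv <- preprocess_subject(s$vol, preproc)
    m <- map_subject(pv, cohort$mask, band, total_band)
    out[[s$group]][[length(out[[s$group]]) + 1L]] <- m
  }
  out
}

#' Simulate a cohort and reduce it to per-subject maps, streaming
#'
#' Equivalent to [simulate_cohort()] followed by [cohort_maps()], but
#' generates, preprocesses and maps one subject at a time so only one 4D
#' volume is in memory at once. Per-subject seeds match
#' [simulate_cohort()] exactly.
#'
#' @inheritParams run_group_pipeline
#' @param config a [sim_config()].
#' @param n_per_group subjects per group (>= 2).
#' @param seed integer seed.
#' @return list: `maps` (as [cohort_maps()]), `atlas`, `mask`.
#' @export
simulate_cohort_maps <- function(config, n_per_group, seed,
                                 preproc = preprocess_config(),
                                 band = c(0.02, 0.07),
                                 total_band = c(0, 0.25)) {
  if (n_per_group < 2L) stop("need n_per_group >= 2 for group statistics")
  mask <- sim_mask(config$grid)
  groups <- rep(c("treatment", "control"), each = n_per_group)
  maps <- list(treatment = list(), control = list())
  for (s in seq_along(groups)) {
    vol <- simulate_subject(config, groups[s], seed = seed * 1000L + s)
    pv <- preprocess_subject(vol, preproc)
    rm(vol)
    maps[[groups[s]]][[length(maps[[groups[s]]]) + 1L]] <-
      map_subject(pv, mask, band, total_band)
  }
  list(maps = maps, atlas = sim_atlas(config), mask = mask)
}

#' Planted-region recovery for one simulation seed
#'
#' Simulates a cohort with one planted amplitude-elevated region, runs the
#' full default pipeline (preprocess, ALFF, mALFF standardization,
#' two-sample t, cluster threshold at voxel p < 0.001 and extent > 36) and
#' reports whether exactly one increase cluster was retained with its peak
#' inside the planted region.
#'
#' @param seed integer simulation seed.
#' @param config a [sim_config()] with planted regions.
#' @param n_per_group subjects per group.
#' @param ... thresholding overrides passed to [run_group_pipeline()].
#' @return list: `recovered` (logical), `clusters` (table),
#'   `n_increase`, `n_decrease`.
#' @export
planted_region_recovery <- function(seed, config = sim_config(),
                                    n_per_group = 20L,
                                    preproc = preprocess_config(),
                                    measure = "alff",
                                    standardize = "divide_by_global_mean",
                                    voxel_p = 0.001, extent = 36L,
                                    connectivity = 26L) {
  sim <- simulate_cohort_maps(config, n_per_group, seed, preproc)
  sel <- lapply(sim$maps, function(g) lapply(g, `[[`, measure))
  res <- group_compare(sel$treatment, sel$control, sim$mask,
                       atlas = sim$atlas, standardize = standardize,
                       voxel_p = voxel_p, extent = extent,
                       connectivity = connectivity)
  cl <- res$clusters
  inc <- cl[cl$sign == "increase", , drop = FALSE]
  in_region <- FALSE
  if (nrow(inc) == 1L) {
    lab <- config$planted_regions[[1]]$label
    d <- dim(sim$atlas$data)
    lin <- inc$peak_k * d[1] * d[2] + inc$peak_j * d[1] + inc$peak_i + 1L
    in_region <- sim$atlas$data[lin] == lab
  }
  list(recovered = nrow(inc) == 1L && in_region, clusters = cl,
       n_increase = nrow(inc), n_decrease = sum(cl$sign == "decrease"))
}

#' Voxel-wise type-I calibration under the null
#'
#' Simulates a cohort with all planted multipliers 1 (no group
#' difference), runs the pipeline and returns the fraction of in-mask
#' voxels with p < `alpha` together with the retained cluster count.
#' Smoothing is disabled by default here so the in-mask voxel p values
#' are independent and the binomial reference distribution for the
#' suprathreshold fraction is exact.
#'
#' @param seed integer simulation seed.
#' @param config a [sim_config()]; its planted multipliers are forced to 1.
#' @param n_per_group subjects per group.
#' @param alpha voxel-level threshold whose exceedance rate is measured.
#' @param smooth_fwhm_mm smoothing width for the null run (default 0).
#' @param ... thresholding overrides for [run_group_pipeline()].
#' @return list: `fraction` (p < alpha), `n_voxels`, `n_clusters`.
#' @export
null_calibration_run <- function(seed, config = sim_config(),
                                 n_per_group = 20L, alpha = 0.05,
                                 smooth_fwhm_mm = 0,
                                 measure = "alff",
                                 standardize = "divide_by_global_mean",
                                 voxel_p = 0.001, extent = 36L,
                                 connectivity = 26L) {
  config$planted_regions <- lapply(config$planted_regions, function(r) {
    r$multiplier <- 1
    r
  })
  pp <- preprocess_config(smooth_fwhm_mm = smooth_fwhm_mm)
  sim <- simulate_cohort_maps(config, n_per_group, seed, pp)
  sel <- lapply(sim$maps, function(g) lapply(g, `[[`, measure))
  res <- group_compare(sel$treatment, sel$control, sim$mask,
                       standardize = standardize, voxel_p = voxel_p,
                       extent = extent, connectivity = connectivity)
  pv <- map_values(res$p)
  list(fraction = mean(pv < alpha), n_voxels = length(pv),
       n_clusters = nrow(res$clusters))
}
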