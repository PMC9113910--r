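#' Simulation configuration for synthetic BOLD cohorts
#'
#' The generator emulates the acquisition geometry of the target study:
#' TR = 2 s, 260 volumes (first 20 discarded downstream), 64x64x30 grid at
#' full scale. The default test grid is reduced (24x24x12) so the full
#' pipeline runs in minutes; `grid = "full"` selects the acquisition
#' geometry.
#'
#' Each voxel's series is a constant baseline plus `n_sinusoids` sinusoids
#' with frequencies drawn uniformly in the low-frequency band and random
#' phases, plus white Gaussian noise. Inside a planted region, the
#' sinusoid amplitudes of the elevated group (`"treatment"`) are multiplied
#' by that region's `multiplier`, planting a controlled group difference in
#' band-limited amplitude whose ground truth is analytic (a sinusoid of
#' amplitude a has variance a^2/2 and in-band spectral amplitude a).
#'
#' @param grid length-3 integer grid shape, or `"full"` for 64x64x30.
#' @param n_timepoints number of volumes (default 260).
#' @param tr_seconds repetition time, s.
#' @param voxel_size_mm voxel edge lengths, mm (defaults to the acquisition
#'   geometry: 220 mm / 64 in-plane, 4 mm slices + 1.2 mm gap).
#' @param baseline constant BOLD baseline intensity.
#' @param n_sinusoids sinusoids per voxel.
#' @param sinusoid_amp base sinusoid amplitude.
#' @param noise_sd white-noise standard deviation.
#' @param band frequency band the sinusoids are drawn from, Hz.
#' @param planted_regions list of `list(label =, multiplier =, dim =)`
#'   planted blocks; `dim` is the block shape in voxels (default 5x4x3 =
#'   60 voxels). Multipliers must be positive.
#' @param onef_background add a 1/f background component for realism tests.
#' @export
sim_config <- function(grid = c(24L, 24L, 12L), n_timepoints = 260L,
                       tr_seconds = 2, voxel_size_mm = c(3.4375, 3.4375, 5.2),
                       baseline = 100, n_sinusoids = 3L, sinusoid_amp = 1,
                       noise_sd = 1, band = c(0.02, 0.07),
                       planted_regions = list(list(label = 1L,
                                                   multiplier = 2,
                                                   dim = c(5L, 4L, 3L))),
                       onef_background = FALSE) {
  if (identical(grid, "full")) grid <- c(64L, 64L, 30L)
  stopifnot(length(grid) == 3L, all(grid >= 4L), n_timepoints >= 8L,
            tr_seconds > 0, noise_sd >= 0, n_sinusoids >= 1L)
  for (r in planted_regions)
    if (is.null(r$multiplier) || r$multiplier <= 0)
      stop("planted region multipliers must be > 0")
  list(grid = as.integer(grid), n_timepoints = as.integer(n_timepoints),
       tr_seconds = tr_seconds, voxel_size_mm = voxel_size_mm,
       baseline = baseline, n_sinusoids = as.integer(n_sinusoids),
       sinusoid_amp = sinusoid_amp, noise_sd = noise_sd, band = band,
       planted_regions = planted_regions, onef_background = onef_background)
}

#' Ellipsoidal brain mask for a simulation grid
#' @param grid length-3 grid shape.
#' @export
sim_mask <- function(grid) {
  ci <- (grid + 1) / 2
  ax <- grid / 2 - 0.5
  ii <- slice.index(array(0, grid), 1)
  jj <- slice.index(array(0, grid), 2)
  kk <- slice.index(array(0, grid), 3)
  ((ii - ci[1]) / ax[1])^2 + ((jj - ci[2]) / ax[2])^2 +
    ((kk - ci[3]) / ax[3])^2 <= 1
}

#' Label atlas with the planted regions of a simulation config
#'
#' Places each planted region as a rectangular block of the configured
#' shape, centred in one hemisphere (blocks are stacked along z if there
#' are several), entirely inside the ellipsoidal mask.
#' @param config a [sim_config()].
#' @export
sim_atlas <- function(config) {
  g <- config$grid
  arr <- array(0L, g)
  nm <- list()
  zoff <- 0L
  for (r in config$planted_regions) {
    bd <- if (is.null(r$dim)) c(5L, 4L, 3L) else as.integer(r$dim)
    # centre of the x-upper hemisphere
    c0 <- c(round(g[1] * 0.68), round(g[2] / 2), round(g[3] / 2)) -
      floor(bd / 2)
    c0[3] <- c0[3] + zoff
    ix <- c0[1] + seq_len(bd[1]) - 1L
    iy <- c0[2] + seq_len(bd[2]) - 1L
    iz <- c0[3] + seq_len(bd[3]) - 1L
    if (any(ix < 1 | ix > g[1]) || any(iy < 1 | iy > g[2]) ||
        any(iz < 1 | iz > g[3]))
      stop("planted region does not fit in the grid")
    arr[ix, iy, iz] <- as.integer(r$label)
    nm[[as.character(r$label)]] <- sprintf("planted_region_%d", r$label)
    zoff <- zoff + bd[3] + 1L
  }
  label_atlas(arr, nm)
}

#' Simulate one subject's 4D BOLD volume
#'
#' Deterministic given `seed`. The random draws (frequencies, phases,
#' noise) do not depend on the group label, so the same seed under
#' different groups yields volumes differing only by the planted
#' amplitude multipliers.
#'
#' @param config a [sim_config()].
#' @param group `"treatment"` (amplitude-elevated in planted regions) or
#'   `"control"`.
#' @param seed integer seed.
#' @return a [ts_volume()].
#' @export
simulate_subject <- function(config, group, seed) {
  if (!group %in% c("treatment", "control"))
    stop("group must be 'treatment' or 'control'")
  g <- config$grid
  nv <- prod(g)
  nt <- config$n_timepoints
  set.seed(as.integer(seed))
  freqs <- matrix(stats::runif(nv * config$n_sinusoids,
                               config$band[1], config$band[2]),
                  nrow = config$n_sinusoids)
  phases <- matrix(stats::runif(nv * config$n_sinusoids, 0, 2 * pi),
                   nrow = config$n_sinusoids)
  noise <- if (config$noise_sd > 0)
    stats::rnorm(nt * nv, sd = config$noise_sd)
  else 0
  amp <- rep(config$sinusoid_amp, nv)
  if (group == "treatment" && length(config$planted_regions)) {
    atlas <- sim_atlas(config)
    for (r in config$planted_regions) {
      inr <- as.vector(atlas$data == as.integer(r$label))
      amp[inr] <- amp[inr] * r$multiplier
    }
  }
  ts <- (seq_len(nt) - 1) * config$tr_seconds
  # voxels-by-time layout so the 4D reshape is copy-free
  sig <- matrix(config$baseline + noise, nv, nt)
  for (j in seq_len(config$n_sinusoids)) {
    ph <- outer(2 * pi * freqs[j, ], ts) + phases[j, ]  # nv x nt, phases
    sig <- sig + amp * sin(ph)                          # recycle by rows
  }
  if (isTRUE(config$onef_background)) {
    # spectrally shaped 1/f noise, same for both groups given the seed
    wn <- matrix(stats::rnorm(nt * nv), nt, nv)
    W <- stats::mvfft(wn)
    f <- pmin(0:(nt - 1), nt - (0:(nt - 1))) / (nt * config$tr_seconds)
    sc <- ifelse(f > 0, 1 / sqrt(f / min(f[f > 0])), 0)
    sig <- sig + t(Re(stats::mvfft(W * sc, inverse = TRUE)) / nt)
  }
  dim(sig) <- c(g, nt)
  .ts_volume_fast(sig, config$tr_seconds, config$voxel_size_mm)
}

#' Simulate a two-group cohort with atlas and mask
#'
#' Per-subject seeds are derived deterministically from `seed`. Treatment
#' subjects carry the planted amplitude elevation; controls do not.
#'
#' @param config a [sim_config()].
#' @param n_per_group subjects per group (>= 2).
#' @param seed integer seed.
#' @return list: `subjects` (list of `list(subject_id, group, vol)`),
#'   `atlas`, `mask`.
#' @export
simulate_cohort <- function(config, n_per_group, seed) {
  if (n_per_group < 2L)
    stop("need n_per_group >= 2 for group statistics")
  groups <- rep(c("treatment", "control"), each = n_per_group)
  subjects <- vector("list", 2L * n_per_group)
  for (s in seq_along(groups)) {
    subjects[[s]] <- list(
      subject_id = sprintf("sub-%03d", s),
      group = groups[s],
      vol = simulate_subject(config, groups[s], seed = seed * 1000L + s))
  }
  list(subjects = subjects, atlas = sim_atlas(config),
       mask = sim_mask(config$grid))
}

#' Clinical simulation configuration
#'
#' Defaults are the target study's printed group summaries: treatment VAS
#' 8.3±1.1 (baseline), 6.5±0.8, 6.5±0.8, 3.1±0.3, 2.3±0.4 points at weeks
#' 1-4; control baseline 8.3±1.2, week-3 5.5±0.5, week-4 4.6±0.5. The
#' control weeks 1-2 are not reported and are linearly interpolated
#' (7.4±0.9, 6.4±0.7) between the printed baseline and week 3 — synthetic,
#' non-reported values. Sleep hours: treatment 3.6±0.3, 4.8±0.5, 5.1±0.4,
#' 5.8±0.6; control 2.5±0.4, 3.3±0.3, 3.9±0.3, 4.1±0.4.
#'
#' @param n_per_group subjects per group.
#' @param vas_mean,vas_sd named list per group: numeric length 5
#'   (baseline, weeks 1-4).
#' @param sleep_mean,sleep_sd named list per group: numeric length 4
#'   (weeks 1-4).
#' @param seed integer seed.
#' @export
clinical_sim_config <- function(
    n_per_group = 20L,
    vas_mean = list(treatment = c(8.3, 6.5, 6.5, 3.1, 2.3),
                    control = c(8.3, 7.4, 6.4, 5.5, 4.6)),
    vas_sd = list(treatment = c(1.1, 0.8, 0.8, 0.3, 0.4),
                  control = c(1.2, 0.9, 0.7, 0.5, 0.5)),
    sleep_mean = list(treatment = c(3.6, 4.8, 5.1, 5.8),
                      control = c(2.5, 3.3, 3.9, 4.1)),
    sleep_sd = list(treatment = c(0.3, 0.5, 0.4, 0.6),
                    control = c(0.4, 0.3, 0.3, 0.4)),
    seed = 1L) {
  stopifnot(n_per_group >= 1L,
            all(unlist(vas_sd) >= 0), all(unlist(sleep_sd) >= 0),
            lengths(vas_mean) == 5L, lengths(sleep_mean) == 4L)
  list(n_per_group = as.integer(n_per_group), vas_mean = vas_mean,
       vas_sd = vas_sd, sleep_mean = sleep_mean, sleep_sd = sleep_sd,
       seed = as.integer(seed))
}

#' Simulate a clinical follow-up table
#'
#' Every cell is drawn Normal(mean, SD) per the config; VAS values are
#' clipped to \[0, 10\] (a deliberate truncation — the configured SDs make
#' clipping rare), sleep hours to >= 0. Deterministic given the seed.
#'
#' @param config a [clinical_sim_config()].
#' @return validated clinical data.frame (see [validate_clinical_table()]).
#' @export
simulate_clinical <- function(config = clinical_sim_config()) {
  set.seed(config$seed)
  n <- config$n_per_group
  rows <- list()
  sid <- 0L
  for (grp in c("treatment", "control")) {
    vm <- config$vas_mean[[grp]]; vs <- config$vas_sd[[grp]]
    sm <- config$sleep_mean[[grp]]; ss <- config$sleep_sd[[grp]]
    vas <- sapply(1:5, function(w) stats::rnorm(n, vm[w], vs[w]))
    slp <- sapply(1:4, function(w) stats::rnorm(n, sm[w], ss[w]))
    vas <- pmin(pmax(vas, 0), 10)
    slp <- pmax(slp, 0)
    df <- data.frame(
      subject_id = sprintf("sub-%03d", sid + seq_len(n)),
      group = grp,
      vas_baseline = vas[, 1], vas_week1 = vas[, 2], vas_week2 = vas[, 3],
      vas_week3 = vas[, 4], vas_week4 = vas[, 5],
      sleep_week1 = slp[, 1], sleep_week2 = slp[, 2],
      sleep_week3 = slp[, 3], sleep_week4 = slp[, 4])
    rows[[grp]] <- df
    sid <- sid + n
  }
  validate_clinical_table(do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Simulate a feature matrix for the classifier comparison
#'
#' `"linear"`: two Gaussian blobs separated along every informative
#' dimension — linearly separable. `"nonlinear"`: an exclusive-or
#' arrangement of four Gaussian blobs in 2 informative dimensions
#' (diagonally opposite blobs share a class, so no linear boundary beats
#' chance while the classes are cleanly separable through a nonlinear
#' transform) plus uniform-noise dimensions. All features lie in \[0, 1\]
#' as required by the cross-entropy reconstruction loss.
#'
#' @param n_per_class samples per class.
#' @param n_features total feature count (>= 2 informative ones).
#' @param structure `"linear"` or `"nonlinear"`.
#' @param seed integer seed.
#' @param separation blob separation (linear) in within-class SD units.
#' @param blob_sd within-blob SD of the informative dimensions
#'   (nonlinear).
#' @return list: `features` (matrix in \[0,1\]), `labels` (factor "A"/"B").
#' @export
simulate_feature_table <- function(n_per_class, n_features = 10L,
                                   structure = c("nonlinear", "linear"),
                                   seed = 1L, separation = 4,
                                   blob_sd = 0.08) {
  structure <- match.arg(structure)
  if (n_features < 2L) stop("need at least 2 features")
  set.seed(as.integer(seed))
  n <- 2L * n_per_class
  labels <- factor(rep(c("A", "B"), each = n_per_class))
  if (structure == "linear") {
    mu <- rep(c(0, separation), each = n_per_class)
    X <- matrix(stats::rnorm(n * n_features), n, n_features) + mu
    rng <- apply(X, 2, range)
    X <- sweep(sweep(X, 2, rng[1, ]), 2,
               pmax(rng[2, ] - rng[1, ], 1e-12), "/")
  } else {
    # XOR layout: class A at (lo,lo) and (hi,hi), class B at (lo,hi),(hi,lo)
    corner <- sample(c(0.25, 0.75), n, replace = TRUE)
    other <- ifelse(labels == "A", corner, 1 - corner)
    X <- cbind(corner + stats::rnorm(n, sd = blob_sd),
               other + stats::rnorm(n, sd = blob_sd),
               matrix(stats::runif(n * (n_features - 2L)),
                      n, n_features - 2L))
    X <- pmin(pmax(X, 0), 1)
  }
  perm <- sample.int(n)   # shuffle rows so splits are class-mixed
  list(features = X[perm, , drop = FALSE], labels = labels[perm])
}
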