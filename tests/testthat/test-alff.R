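test_that("the periodogram recovers sinusoid amplitudes and satisfies Parseval", {
  n <- 240; tr <- 2
  t_s <- (0:(n - 1)) * tr
  # 0.05 Hz sits exactly on bin k = 0.05 * n * tr = 24
  x <- 3 * sin(2 * pi * 0.05 * t_s + 1)
  sp <- periodogram(x, tr)
  expect_equal(which.max(sp$amplitude) - 1L, 24L)
  expect_equal(sp$amplitude[25], 3, tolerance = 1e-10)
  expect_lt(max(sp$amplitude[-25]), 1e-10)
  expect_equal(sp$frequencies_hz[25], 0.05)

  # Parseval under the chosen normalization (population variance + mean^2)
  set.seed(5)
  y <- rnorm(n, mean = 2)
  spy <- periodogram(y, tr)
  expect_equal(sum(spy$power), mean(y^2), tolerance = 1e-8)

  expect_equal(periodogram(rep(0, n), tr)$amplitude, rep(0, 121))
  expect_error(periodogram(c(y[1:10], NaN, y[12:n]), tr), "NA")
  expect_error(periodogram(rnorm(5), tr), "too short")
})

test_that("ALFF is the mean in-band amplitude with the documented bin count", {
  n <- 240; tr <- 2
  t_s <- (0:(n - 1)) * tr
  # closed-interval band rule: bins k = 10..33, i.e. 24 bins
  f <- (0:120) / (n * tr)
  expect_identical(sum(f >= 0.02 & f <= 0.07), 24L)

  x <- 2 * sin(2 * pi * 0.05 * t_s)     # single in-band bin tone
  sp <- periodogram(x, tr)
  expect_equal(compute_alff(sp), 2 / 24, tolerance = 1e-10)

  # out-of-band-only signal
  z <- sin(2 * pi * 0.15 * t_s)
  expect_lt(compute_alff(periodogram(z, tr)), 1e-10)

  # homogeneity: doubling the series doubles ALFF
  set.seed(6)
  r <- rnorm(n)
  expect_equal(compute_alff(periodogram(2 * r, tr)),
               2 * compute_alff(periodogram(r, tr)), tolerance = 1e-10)

  expect_error(compute_alff(sp, band = c(0.021, 0.0211)), "no spectrum bins")
})

test_that("ALFF equals a filter-then-measure time-domain oracle", {
  # oracle: ideal band-pass the series, then take the mean amplitude of the
  # filtered series over the same bins — an independent route to the same
  # quantity
  tr <- 2
  set.seed(7)
  for (i in 1:100) {
    n <- sample(c(120, 240, 300), 1)
    x <- rnorm(n) + sin(2 * pi * runif(1, 0.01, 0.2) * (0:(n - 1)) * tr)
    direct <- compute_alff(periodogram(x, tr))
    filt <- bandpass(x, tr, 0.02, 0.07)
    spf <- periodogram(filt, tr)
    idx <- spf$frequencies_hz >= 0.02 & spf$frequencies_hz <= 0.07
    oracle <- sum(spf$amplitude[idx]) / sum(idx)
    expect_equal(direct, oracle, tolerance = 1e-8)
  }
})

test_that("f-ALFF is a bounded band-amplitude fraction", {
  n <- 240; tr <- 2
  t_s <- (0:(n - 1)) * tr
  # all signal power inside the band: f-ALFF -> 1 as noise -> 0
  pure <- sin(2 * pi * 0.05 * t_s)
  expect_equal(compute_falff(periodogram(pure, tr)), 1, tolerance = 1e-9)
  # signal entirely out of band
  expect_lt(compute_falff(periodogram(sin(2 * pi * 0.15 * t_s), tr)), 1e-9)
  # zero series: denominator zero -> 0
  expect_identical(compute_falff(periodogram(rep(0, n), tr)), 0)
  expect_error(compute_falff(periodogram(pure, tr), band = c(0.01, 0.3)),
               "contained")

  # bounds and scale invariance on random series
  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(240) + 0.5 * sin(2 * pi * runif(1, 0.01, 0.24) * t_s)
    v <- compute_falff(periodogram(x, tr))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(compute_falff(periodogram(3 * x, tr)), v, tolerance = 1e-10)
  }
})

test_that("subject maps apply the spectral measures voxel-wise inside the mask", {
  cfg <- tiny_sim_config()
  vol <- preprocess_subject(simulate_subject(cfg, "treatment", 9),
                            preprocess_config(n_discard = 0, n_keep = 60,
                                              smooth_fwhm_mm = 0))
  mask <- sim_mask(cfg$grid)
  m <- map_subject(vol, mask)
  expect_true(all(is.na(m$alff$data[!mask])))
  v <- sample(which(mask), 5)
  for (lin in v) {
    idx <- arrayInd(lin, cfg$grid)
    series <- vol$data[idx[1], idx[2], idx[3], ]
    expect_equal(m$alff$data[lin],
                 compute_alff(periodogram(series, cfg$tr_seconds)),
                 tolerance = 1e-10)
    expect_equal(m$falff$data[lin],
                 compute_falff(periodogram(series, cfg$tr_seconds)),
                 tolerance = 1e-10)
  }

  # single-voxel mask gives a scalar map
  m1 <- map_subject(vol, array(seq_len(prod(cfg$grid)) == v[1], cfg$grid))
  expect_identical(sum(!is.na(m1$alff$data)), 1L)
})

test_that("map standardization has the stated fixed points", {
  dims <- c(6, 5, 4)
  mask <- array(runif(prod(dims)) > 0.4, dims); mask[1] <- TRUE
  m <- random_stat_map(dims, mask, seed = 10)
  dv <- standardize_map(m, "divide_by_global_mean")
  expect_equal(mean(map_values(dv)), 1, tolerance = 1e-10)
  zs <- standardize_map(m, "zscore")
  expect_lt(abs(mean(map_values(zs))), 1e-10)
  expect_equal(sd(map_values(zs)), 1, tolerance = 1e-10)

  const <- stat_map(array(3, dims), "alff", mask)
  expect_equal(map_values(standardize_map(const)), rep(1, sum(mask)))

  zero <- stat_map(array(0, dims), "alff", mask)
  expect_error(standardize_map(zero), "zero")

  # divide mode commutes with global intensity scaling
  m2 <- m; m2$data <- m$data * 7
  expect_equal(map_values(standardize_map(m2)), map_values(dv),
               tolerance = 1e-12)
})

test_that("scale equivariance: c*x scales ALFF by c and leaves f-ALFF fixed", {
  cfg <- tiny_sim_config()
  vol <- preprocess_subject(simulate_subject(cfg, "control", 12),
                            preprocess_config(n_discard = 0, n_keep = 60,
                                              smooth_fwhm_mm = 0))
  mask <- sim_mask(cfg$grid)
  m1 <- map_subject(vol, mask)
  vol2 <- vol; vol2$data <- vol$data * 2.5
  m2 <- map_subject(vol2, mask)
  expect_equal(map_values(m2$alff), 2.5 * map_values(m1$alff),
               tolerance = 1e-10)
  expect_equal(map_values(m2$falff), map_values(m1$falff), tolerance = 1e-10)
})

test_that("f-ALFF suppresses broadband-noise signals that ALFF amplifies", {
  pp <- preprocess_config(n_discard = 0, n_keep = 120, smooth_fwhm_mm = 0)

  # map level: a pure-broadband-noise compartment (a ventricle stand-in)
  # shows up as elevated standardized ALFF but suppressed f-ALFF
  cfg <- sim_config(grid = c(12, 12, 8), n_timepoints = 120,
                    planted_regions = list())
  mask <- sim_mask(cfg$grid)
  block <- array(FALSE, cfg$grid); block[5:8, 5:8, 3:5] <- TRUE
  block <- block & mask
  set.seed(50)
  v <- simulate_subject(cfg, "control", 1)
  idx <- which(block)
  for (t in seq_len(dim(v$data)[4])) {
    fr <- v$data[, , , t]
    fr[idx] <- fr[idx] + rnorm(length(idx), sd = 3)
    v$data[, , , t] <- fr
  }
  m <- map_subject(preprocess_subject(v, pp), mask)
  malff <- standardize_map(m$alff)
  mfalff <- standardize_map(m$falff)
  expect_gt(mean(malff$data[block]), 1.2)   # noise reads as activation
  expect_lt(mean(mfalff$data[block]), 1)    # fraction measure suppresses it
  expect_lt(mean(mfalff$data[block]), mean(malff$data[block]))

  # group level: with a real effect elsewhere, global-mean standardization
  # leaks the amplitude elevation into no-effect voxels for ALFF far more
  # than for the scale-free f-ALFF
  cfg2 <- sim_config(grid = c(12, 12, 8), n_timepoints = 120,
                     planted_regions = list(list(label = 1L, multiplier = 3,
                                                 dim = c(6L, 5L, 4L))))
  sim <- simulate_cohort_maps(cfg2, 8, 77, pp)
  noeff <- sim$mask & !(sim_atlas(cfg2)$data == 1L)
  mean_abs_t <- vapply(c("alff", "falff"), function(meas) {
    A <- lapply(sim$maps$treatment, function(x) standardize_map(x[[meas]]))
    B <- lapply(sim$maps$control, function(x) standardize_map(x[[meas]]))
    tt <- two_sample_t_map(A, B, sim$mask)
    mean(abs(tt$t$data[noeff]))
  }, 0)
  expect_lt(mean_abs_t["falff"], mean_abs_t["alff"])
})
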