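test_that("voxel-wise two-sample t agrees with the reference routine", {
  dims <- c(5, 4, 3)
  mask <- array(TRUE, dims)
  set.seed(20)
  A <- lapply(1:6, function(i) array(rnorm(prod(dims)), dims))
  B <- lapply(1:7, function(i) array(rnorm(prod(dims), mean = 0.3), dims))
  res <- two_sample_t_map(A, B, mask)
  expect_identical(res$df, 11)
  for (lin in sample(prod(dims), 8)) {
    a <- vapply(A, `[`, 0, lin); b <- vapply(B, `[`, 0, lin)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$t$data[lin], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p$data[lin], ref$p.value, tolerance = 1e-10)
  }

  # identical groups: t = 0, p = 1 at every voxel
  same <- two_sample_t_map(A, A, mask)
  expect_equal(map_values(same$t), rep(0, prod(dims)))
  expect_equal(map_values(same$p), rep(1, prod(dims)))
  # constant maps: zero pooled variance handled as t = 0, p = 1, logged
  C <- lapply(1:3, function(i) array(2, dims))
  deg <- two_sample_t_map(C, C, mask)
  expect_identical(deg$n_degenerate, as.integer(prod(dims)))
  expect_equal(map_values(deg$p), rep(1, prod(dims)))
  expect_error(two_sample_t_map(A[1], B, mask), "at least 2")
})

test_that("voxel-wise two-sample t is calibrated under the null", {
  dims <- c(10, 10, 10)   # 1000 voxels
  mask <- array(TRUE, dims)
  set.seed(21)
  A <- lapply(1:20, function(i) array(rnorm(prod(dims)), dims))
  B <- lapply(1:20, function(i) array(rnorm(prod(dims)), dims))
  res <- two_sample_t_map(A, B, mask)
  frac <- mean(map_values(res$p) < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("paired t matches the reference and handles degenerate variance", {
  dims <- c(4, 4, 2)
  mask <- array(TRUE, dims)
  set.seed(22)
  before <- lapply(1:9, function(i) array(rnorm(prod(dims)), dims))
  after <- lapply(before, function(m) m + array(rnorm(prod(dims), 0.5), dims))
  res <- paired_t_map(before, after, mask)
  expect_identical(res$df, 8)
  for (lin in sample(prod(dims), 5)) {
    b <- vapply(before, `[`, 0, lin); a <- vapply(after, `[`, 0, lin)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(res$t$data[lin], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p$data[lin], ref$p.value, tolerance = 1e-10)
  }

  # after = before + constant: zero-variance differences, p floored at 0
  # (dyadic grid values keep the shift exact in floating point)
  before <- lapply(before, function(m) round(m * 4) / 4)
  shift <- lapply(before, function(m) m + 2)
  deg <- paired_t_map(before, shift, mask)
  expect_true(all(is.infinite(map_values(deg$t))))
  expect_equal(map_values(deg$p), rep(0, prod(dims)))
  expect_identical(deg$n_degenerate, as.integer(prod(dims)))

  expect_error(paired_t_map(before, after[1:5], mask), "same subjects")

  # paired and unpaired disagree on correlated data
  two <- two_sample_t_map(after, before, mask)
  expect_gt(mean(abs(map_values(res$t))), mean(abs(map_values(two$t))))
})

test_that("connected components equal a brute-force flood fill", {
  set.seed(23)
  for (rep in 1:30) {
    dims <- c(sample(4:8, 1), sample(4:8, 1), sample(3:6, 1))
    fg <- array(runif(prod(dims)) < 0.4, dims)
    for (conn in c(6, 18, 26)) {
      mine <- connected_components(fg, conn)
      oracle <- floodfill_components(fg, conn)
      expect_true(same_partition(mine, oracle))
      expect_identical(sort(tabulate(mine)), sort(tabulate(oracle)))
    }
  }
  expect_error(connected_components(array(TRUE, c(2, 2, 2)), 10),
               "connectivity")
})

test_that("cluster extent thresholding is strict and sorted as documented", {
  dims <- c(12, 10, 8)
  mask <- array(TRUE, dims)
  t_arr <- array(0, dims); p_arr <- array(1, dims)
  # component of 40 voxels (5x4x2) and one of 10 voxels (5x2x1)
  t_arr[2:6, 2:5, 2:3] <- 5; p_arr[2:6, 2:5, 2:3] <- 1e-5
  t_arr[8:12, 8:9, 6] <- 4;  p_arr[8:12, 8:9, 6] <- 1e-5
  maps <- tp_maps(t_arr, p_arr)
  tab <- cluster_threshold(maps$t, maps$p, voxel_p = 0.001, extent = 36)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$size_voxels, 40L)
  expect_identical(tab$sign, "increase")

  # a component of exactly 36 voxels is discarded at extent 36
  t36 <- array(0, dims); p36 <- array(1, dims)
  t36[1:6, 1:6, 1] <- 3; p36[1:6, 1:6, 1] <- 1e-5
  m36 <- tp_maps(t36, p36)
  expect_identical(nrow(cluster_threshold(m36$t, m36$p, extent = 36)), 0L)
  expect_identical(nrow(cluster_threshold(m36$t, m36$p, extent = 35)), 1L)

  # all-suprathreshold 5x5x5 mask: one cluster of 125
  small_mask <- array(TRUE, c(5, 5, 5))
  all1 <- tp_maps(array(2, c(5, 5, 5)), array(1e-5, c(5, 5, 5)), small_mask)
  tab125 <- cluster_threshold(all1$t, all1$p, extent = 0)
  expect_identical(nrow(tab125), 1L)
  expect_identical(tab125$size_voxels, 125L)

  # sign splitting and size-descending order
  t2 <- array(0, dims); p2 <- array(1, dims)
  t2[2:6, 2:5, 2:3] <- 5; p2[2:6, 2:5, 2:3] <- 1e-5     # +, 40 vox
  t2[8:12, 1:6, 4:5] <- -6; p2[8:12, 1:6, 4:5] <- 1e-5  # -, 60 vox
  m2 <- tp_maps(t2, p2)
  tab2 <- cluster_threshold(m2$t, m2$p, extent = 36)
  expect_identical(tab2$sign, c("decrease", "increase"))
  expect_identical(tab2$size_voxels, c(60L, 40L))
  expect_identical(tab2$cluster_id, 1:2)

  # peak voxel is 0-based and maps to mm through the affine
  aff <- diag(c(3, 3, 4, 1))
  m3 <- tp_maps(t_arr, p_arr, mask, aff)
  tab3 <- cluster_threshold(m3$t, m3$p, extent = 36)
  expect_equal(tab3$peak_x_mm, tab3$peak_i * 3)
  expect_equal(tab3$peak_z_mm, tab3$peak_k * 4)
})

test_that("thresholding is monotone in extent and voxel p", {
  set.seed(24)
  dims <- c(10, 10, 6)
  mask <- array(TRUE, dims)
  A <- lapply(1:8, function(i) array(rnorm(prod(dims)), dims))
  B <- lapply(1:8, function(i) array(rnorm(prod(dims), 0.8), dims))
  res <- two_sample_t_map(A, B, mask)
  counts <- vapply(c(0, 5, 10, 20, 40), function(ext)
    nrow(cluster_threshold(res$t, res$p, voxel_p = 0.05, extent = ext)), 0L)
  expect_true(all(diff(counts) <= 0))
  supra <- vapply(c(0.001, 0.01, 0.05, 0.1), function(vp)
    sum(map_values(res$p) < vp), 0L)
  expect_true(all(diff(supra) >= 0))
})

test_that("cluster labelling reads the atlas at the peak", {
  dims <- c(12, 10, 8)
  t_arr <- array(0, dims); p_arr <- array(1, dims)
  t_arr[2:6, 2:5, 2:3] <- 5; p_arr[2:6, 2:5, 2:3] <- 1e-5
  maps <- tp_maps(t_arr, p_arr)
  tab <- cluster_threshold(maps$t, maps$p, extent = 36)

  grid <- array(0L, dims)
  grid[2:6, 2:5, 2:3] <- 3L
  atl <- label_atlas(grid, list(`3` = "planted"))
  lt <- label_clusters(tab, atl)
  expect_identical(lt$region_label, "planted")

  # background peak -> unlabeled
  atl0 <- label_atlas(array(0L, dims), list())
  expect_identical(label_clusters(tab, atl0)$region_label, "unlabeled")

  # renaming regions never changes sizes
  atl2 <- label_atlas(grid, list(`3` = "renamed"))
  lt2 <- label_clusters(tab, atl2)
  expect_identical(lt2$size_voxels, lt$size_voxels)
  expect_identical(lt2$region_label, "renamed")
})
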