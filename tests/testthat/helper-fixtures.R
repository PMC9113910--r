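# Shared fixtures and independent oracles for the test suite.

# small simulation config so unit tests run in seconds
tiny_sim_config <- function(...) {
  sim_config(grid = c(10L, 10L, 6L), n_timepoints = 60L,
             planted_regions = list(list(label = 1L, multiplier = 2,
                                         dim = c(3L, 2L, 2L))), ...)
}

random_stat_map <- function(dims, mask = NULL, kind = "alff", seed = 1) {
  set.seed(seed)
  if (is.null(mask)) mask <- array(TRUE, dims)
  arr <- array(abs(rnorm(prod(dims))) + 0.1, dims)
  stat_map(arr, kind, mask)
}

# Independent flood-fill oracle for connected components: iterative
# depth-first with an explicit stack and scalar neighbour loops — a
# deliberately different algorithm and code path from the package's
# vectorized breadth-first labelling.
floodfill_components <- function(fg, connectivity) {
  d <- dim(fg)
  offs <- switch(as.character(connectivity),
                 "6" = rbind(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0),
                             c(0,0,-1), c(0,0,1)),
                 "18" = {
                   g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                   g[rowSums(abs(g)) %in% 1:2, , drop = FALSE]
                 },
                 "26" = {
                   g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                   g[rowSums(abs(g)) > 0, , drop = FALSE]
                 })
  labels <- array(0L, d)
  lab <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!fg[i, j, k] || labels[i, j, k] != 0L) next
    lab <- lab + 1L
    stack <- list(c(i, j, k))
    labels[i, j, k] <- lab
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (any(w < 1L) || any(w > d)) next
        if (fg[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- lab
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
  }
  labels
}

# same-partition check that is invariant to label numbering
same_partition <- function(lab1, lab2) {
  if (!identical(lab1 > 0L, lab2 > 0L)) return(FALSE)
  fg <- which(lab1 > 0L)
  if (!length(fg)) return(TRUE)
  key1 <- lab1[fg]; key2 <- lab2[fg]
  # bijection between label sets
  m12 <- tapply(key2, key1, function(v) length(unique(v)))
  m21 <- tapply(key1, key2, function(v) length(unique(v)))
  all(m12 == 1L) && all(m21 == 1L)
}

# Brute-force dense 3D Gaussian convolution with replicate (nearest-edge)
# padding: direct nested sums, the oracle for gaussian_smooth().
dense_gauss_oracle <- function(vol, fwhm_mm, voxel_size_mm) {
  d <- dim(vol)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  kern <- lapply(1:3, function(ax) {
    r <- max(1L, ceiling(4 * sig[ax]))
    w <- exp(-((-r):r)^2 / (2 * sig[ax]^2))
    list(r = r, w = w / sum(w))
  })
  clamp <- function(x, n) pmin(pmax(x, 1L), n)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in -kern[[1]]$r:kern[[1]]$r)
      for (b in -kern[[2]]$r:kern[[2]]$r)
        for (cc in -kern[[3]]$r:kern[[3]]$r) {
          acc <- acc + kern[[1]]$w[a + kern[[1]]$r + 1L] *
            kern[[2]]$w[b + kern[[2]]$r + 1L] *
            kern[[3]]$w[cc + kern[[3]]$r + 1L] *
            vol[clamp(i + a, d[1]), clamp(j + b, d[2]), clamp(k + cc, d[3])]
        }
    out[i, j, k] <- acc
  }
  out
}

# construct a vector with exactly the requested sample mean and SD
vector_with_summary <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  x * sd + mean
}

# t/p stat_map pair from explicit arrays (for cluster tests)
tp_maps <- function(t_arr, p_arr, mask = array(TRUE, dim(t_arr)),
                    affine = diag(4)) {
  list(t = stat_map(t_arr, "t", mask, affine),
       p = stat_map(p_arr, "p", mask, affine))
}
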