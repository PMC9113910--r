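#' Voxel-wise two-sample t test
#'
#' Pooled-variance Student t at every in-mask voxel (df = nA + nB - 2),
#' two-sided p from the t distribution. Pooled variance (not Welch) is the
#' classical group t test; group sizes in the target design are equal.
#' Voxels with zero pooled variance get t = 0, p = 1; their count is
#' recorded in the `"n_degenerate"` attribute of the returned list.
#'
#' @param mapsA,mapsB lists of [stat_map()]s (or 3D arrays), one per
#'   subject; at least 2 per group, all the same shape.
#' @param mask 3D logical array.
#' @return list with `t` and `p` [stat_map()]s and `df`.
#' @export
two_sample_t_map <- function(mapsA, mapsB, mask) {
  A <- .stack_maps(mapsA, mask)            # voxels x nA
  B <- .stack_maps(mapsB, mask)
  nA <- ncol(A); nB <- ncol(B)
  if (nA < 2L || nB < 2L) stop("need at least 2 subjects per group")
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tval <- ifelse(se == 0, 0, (mA - mB) / se)
  pval <- ifelse(se == 0, 1, 2 * stats::pt(-abs(tval), df))
  res <- .t_maps_from_vectors(tval, pval, mask, .map_affine(mapsA))
  res$df <- df
  res$n_degenerate <- sum(se == 0)
  res
}

#' Voxel-wise paired t test
#'
#' One-sample t on within-subject differences (after - before), df = n - 1.
#' Zero-variance differences with a nonzero mean give t = +/-Inf and p = 0
#' (degenerate-variance policy); zero mean gives t = 0, p = 1.
#'
#' @param maps_before,maps_after per-subject maps, same subjects in the
#'   same order.
#' @param mask 3D logical array.
#' @export
paired_t_map <- function(maps_before, maps_after, mask) {
  A <- .stack_maps(maps_before, mask)
  B <- .stack_maps(maps_after, mask)
  if (ncol(A) != ncol(B))
    stop("paired test needs the same subjects before and after")
  n <- ncol(A)
  if (n < 2L) stop("need at least 2 subjects")
  D <- B - A
  md <- rowMeans(D)
  sdd <- sqrt(rowSums((D - md)^2) / (n - 1))
  se <- sdd / sqrt(n)
  df <- n - 1
  tval <- ifelse(se == 0, ifelse(md == 0, 0, sign(md) * Inf), md / se)
  pval <- ifelse(se == 0, ifelse(md == 0, 1, 0),
                 2 * stats::pt(-abs(md / ifelse(se == 0, 1, se)), df))
  pval[se == 0 & md != 0] <- 0
  res <- .t_maps_from_vectors(tval, pval, mask, .map_affine(maps_before))
  res$df <- df
  res$n_degenerate <- sum(se == 0 & md != 0)
  res
}

.map_affine <- function(maps) {
  m <- maps[[1]]
  if (inherits(m, "stat_map")) m$affine else diag(4)
}

.stack_maps <- function(maps, mask) {
  vapply(maps, function(m) {
    arr <- if (inherits(m, "stat_map")) m$data else m
    if (!identical(dim(arr), dim(mask))) stop("map/mask shape mismatch")
    arr[mask]
  }, numeric(sum(mask)))
}

.t_maps_from_vectors <- function(tval, pval, mask, affine) {
  ta <- array(NA_real_, dim(mask)); ta[mask] <- tval
  pa <- array(NA_real_, dim(mask)); pa[mask] <- pval
  list(t = stat_map(ta, "t", mask, affine),
       p = stat_map(pa, "p", mask, affine))
}

#' Connected components of a 3D logical array
#'
#' Breadth-first labelling at 6 (face), 18 (face+edge) or 26 (face+edge+
#' vertex) connectivity. Returns an integer array of the same shape with
#' 0 outside the foreground and labels 1..k inside.
#'
#' @param fg 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @export
connected_components <- function(fg, connectivity = 26L) {
  stopifnot(length(dim(fg)) == 3L)
  offs <- .neighbour_offsets(connectivity)
  d <- dim(fg)
  labels <- array(0L, d)
  idx_fg <- which(fg)
  if (!length(idx_fg)) return(labels)
  coord <- arrayInd(idx_fg, d)
  # map linear index -> row in coord for O(1) membership
  infg <- array(0L, d); infg[idx_fg] <- seq_along(idx_fg)
  visited <- logical(length(idx_fg))
  lab <- 0L
  for (s in seq_along(idx_fg)) {
    if (visited[s]) next
    lab <- lab + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      cur <- coord[queue, , drop = FALSE]
      labels[idx_fg[queue]] <- lab
      nb_i <- rep(cur[, 1], each = nrow(offs)) + offs[, 1]
      nb_j <- rep(cur[, 2], each = nrow(offs)) + offs[, 2]
      nb_k <- rep(cur[, 3], each = nrow(offs)) + offs[, 3]
      ok <- nb_i >= 1L & nb_i <= d[1] & nb_j >= 1L & nb_j <= d[2] &
        nb_k >= 1L & nb_k <= d[3]
      lin <- (nb_k[ok] - 1L) * d[1] * d[2] + (nb_j[ok] - 1L) * d[1] + nb_i[ok]
      rows <- infg[lin]
      rows <- rows[rows > 0L]
      rows <- unique(rows[!visited[rows]])
      visited[rows] <- TRUE
      queue <- rows
    }
  }
  labels
}

.neighbour_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  unname(g[keep, , drop = FALSE])
}

#' Cluster-extent thresholding of a voxel-wise t map
#'
#' Binarizes at the voxel threshold `p < voxel_p` (strict), splits the
#' suprathreshold set by the sign of t into increase/decrease components,
#' labels connected components at the configured connectivity, and retains
#' only components with `size > extent` voxels (strict, matching the
#' "voxel size > 36" convention). Rows are sorted by size descending, ties
#' by peak |t| descending, then lexicographic peak voxel index.
#'
#' Peak voxel indices are reported 0-based; peak world coordinates (mm)
#' come from the map affine.
#'
#' @param t_map,p_map voxel-wise statistic maps sharing a mask.
#' @param voxel_p voxel-level p threshold (default 0.001).
#' @param extent minimum cluster extent; clusters of exactly `extent`
#'   voxels are discarded (default 36).
#' @param connectivity 6, 18 or 26 (default 26, vertex-adjacent).
#' @return data.frame: cluster_id, size_voxels, peak_i/j/k (0-based),
#'   peak_x/y/z_mm, peak_t, sign, region_label (filled by
#'   [label_clusters()], `NA` here).
#' @export
cluster_threshold <- function(t_map, p_map, voxel_p = 0.001, extent = 36L,
                              connectivity = 26L) {
  stopifnot(inherits(t_map, "stat_map"), inherits(p_map, "stat_map"))
  if (!identical(dim(t_map$data), dim(p_map$data)))
    stop("t and p maps have different shapes")
  if (!(voxel_p > 0 && voxel_p < 1)) stop("voxel_p must be in (0, 1)")
  if (extent < 0) stop("extent must be >= 0")
  mask <- t_map$mask
  supra <- !is.na(p_map$data) & p_map$data < voxel_p & mask
  rows <- list()
  for (sgn in c("increase", "decrease")) {
    fg <- supra & !is.na(t_map$data) &
      (if (sgn == "increase") t_map$data > 0 else t_map$data < 0)
    labs <- connected_components(fg, connectivity)
    k <- max(labs)
    if (k == 0L) next
    for (cl in seq_len(k)) {
      vox <- which(labs == cl)
      size <- length(vox)
      if (size <= extent) next
      tv <- t_map$data[vox]
      peak_lin <- vox[which.max(abs(tv))]
      pk <- arrayInd(peak_lin, dim(mask))[1, ]
      mm <- (t_map$affine %*% c(pk - 1L, 1))[1:3]
      rows[[length(rows) + 1L]] <- data.frame(
        size_voxels = size,
        peak_i = pk[1] - 1L, peak_j = pk[2] - 1L, peak_k = pk[3] - 1L,
        peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3],
        peak_t = t_map$data[peak_lin], sign = sgn,
        region_label = NA_character_)
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster_id = integer(), size_voxels = integer(),
                      peak_i = integer(), peak_j = integer(),
                      peak_k = integer(), peak_x_mm = numeric(),
                      peak_y_mm = numeric(), peak_z_mm = numeric(),
                      peak_t = numeric(), sign = character(),
                      region_label = character()))
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$size_voxels, -abs(tab$peak_t),
               tab$peak_i, tab$peak_j, tab$peak_k)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(cluster_id = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' Attach atlas region names to a cluster table
#'
#' Each cluster is labelled by the atlas region at its peak voxel;
#' background (label 0) peaks are labelled `"unlabeled"`.
#'
#' @param table cluster table from [cluster_threshold()].
#' @param atlas a [label_atlas()].
#' @export
label_clusters <- function(table, atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (!nrow(table)) return(table)
  d <- dim(atlas$data)
  lin <- (table$peak_k) * d[1] * d[2] + (table$peak_j) * d[1] +
    table$peak_i + 1L
  lab <- atlas$data[lin]
  table$region_label <- vapply(lab, function(l) {
    if (l == 0L) "unlabeled" else as.character(atlas$names[[as.character(l)]])
  }, character(1))
  table
}

#' Run the group comparison on a set of per-subject maps
#'
#' Convenience wrapper: standardize each subject's map, run the voxel-wise
#' test, threshold clusters, label regions.
#'
#' @param mapsA,mapsB lists of per-subject [stat_map()]s.
#' @param mask 3D logical array.
#' @param atlas optional [label_atlas()] for region names.
#' @param standardize standardization mode passed to [standardize_map()],
#'   or `"none"`.
#' @param test `"two_sample"` or `"paired"`.
#' @param voxel_p,extent,connectivity cluster thresholding settings.
#' @return list: `t`, `p` maps, `df`, `clusters` table.
#' @export
group_compare <- function(mapsA, mapsB, mask, atlas = NULL,
                          standardize = "divide_by_global_mean",
                          test = c("two_sample", "paired"),
                          voxel_p = 0.001, extent = 36L,
                          connectivity = 26L) {
  test <- match.arg(test)
  if (standardize != "none") {
    mapsA <- lapply(mapsA, standardize_map, mode = standardize)
    mapsB <- lapply(mapsB, standardize_map, mode = standardize)
  }
  res <- if (test == "two_sample") two_sample_t_map(mapsA, mapsB, mask)
         else paired_t_map(mapsA, mapsB, mask)
  tab <- cluster_threshold(res$t, res$p, voxel_p, extent, connectivity)
  if (!is.null(atlas)) tab <- label_clusters(tab, atlas)
  res$clusters <- tab
  res
}
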