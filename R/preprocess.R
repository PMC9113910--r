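#' Preprocessing configuration
#'
#' Defaults follow the acquisition protocol the pipeline targets: 260
#' acquired volumes of which the first 20 are discarded (240 retained,
#' TR = 2 s), linear detrending, Gaussian spatial smoothing, and the
#' 0.02-0.07 Hz low-frequency band.
#'
#' @param n_discard initial volumes dropped (scanner equilibration).
#' @param n_keep volumes retained after the discard.
#' @param smooth_fwhm_mm Gaussian smoothing kernel FWHM in mm (0 = none).
#'   The protocol never fixes a width; 6 mm is the field convention.
#' @param band_low_hz,band_high_hz low-frequency band edges in Hz.
#' @export
preprocess_config <- function(n_discard = 20L, n_keep = 240L,
                              smooth_fwhm_mm = 6, band_low_hz = 0.02,
                              band_high_hz = 0.07) {
  if (n_discard < 0 || n_keep < 1) stop("invalid discard/keep counts")
  if (!(band_low_hz >= 0 && band_low_hz < band_high_hz))
    stop("need 0 <= band_low < band_high")
  if (smooth_fwhm_mm < 0) stop("smoothing FWHM must be >= 0")
  list(n_discard = as.integer(n_discard), n_keep = as.integer(n_keep),
       smooth_fwhm_mm = smooth_fwhm_mm,
       band_low_hz = band_low_hz, band_high_hz = band_high_hz)
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` frames and keeps the next `n_keep`, in
#' acquisition order.
#'
#' @param vol a [ts_volume()].
#' @param n_discard,n_keep frame counts; the series must contain at least
#'   `n_discard + n_keep` frames.
#' @export
discard_initial <- function(vol, n_discard = 20L, n_keep = 240L) {
  stopifnot(inherits(vol, "ts_volume"))
  nt <- dim(vol$data)[4]
  if (n_discard + n_keep > nt)
    stop(sprintf("series has %d frames; cannot discard %d and keep %d",
                 nt, n_discard, n_keep), call. = FALSE)
  keep <- seq.int(n_discard + 1L, n_discard + n_keep)
  .ts_volume_fast(vol$data[, , , keep, drop = FALSE], vol$tr_seconds,
                  vol$voxel_size_mm, vol$affine)
}

#' Remove linear drift
#'
#' Least-squares removal of intercept and slope from each time series; the
#' output has zero mean and zero linear trend. The mean is removed along
#' with the slope so no DC component survives into spectral normalisation.
#'
#' @param x numeric vector (one series) or matrix (time x series, each
#'   column detrended independently).
#' @export
detrend_linear <- function(x) {
  if (is.matrix(x)) n <- nrow(x) else n <- length(x)
  if (n < 3L) stop("need at least 3 timepoints to detrend")
  tc <- seq_len(n) - (n + 1) / 2          # centred time index
  ss <- sum(tc^2)
  if (is.matrix(x)) {
    xc <- sweep(x, 2L, colMeans(x))
    slope <- as.numeric(crossprod(tc, xc)) / ss
    xc - outer(tc, slope)
  } else {
    xc <- x - mean(x)
    xc - tc * (sum(tc * xc) / ss)
  }
}

#' @rdname detrend_linear
#' @param vol a [ts_volume()]; detrending is applied voxel-wise.
#' @export
detrend_volume <- function(vol) {
  stopifnot(inherits(vol, "ts_volume"))
  d <- dim(vol$data)
  nt <- d[4]
  if (nt < 3L) stop("need at least 3 timepoints to detrend")
  m <- vol$data
  dim(m) <- c(prod(d[1:3]), nt)                 # voxels x time, copy-free
  tc <- seq_len(nt) - (nt + 1) / 2
  xc <- m - rowMeans(m)
  slope <- (xc %*% tc) / sum(tc^2)
  out <- xc - tcrossprod(slope, tc)
  dim(out) <- d
  .ts_volume_fast(out, vol$tr_seconds, vol$voxel_size_mm, vol$affine)
}

# 1D discrete Gaussian smoothing matrix with nearest-edge (replicate)
# boundary handling: tap weight falling outside the grid accrues to the
# nearest edge sample, so constants are preserved exactly and total
# intensity is conserved for interior-supported inputs.
.gauss_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  offs <- (-r):r
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + offs, 1L), n)      # clamp = replicate padding
    for (m in seq_along(j)) K[i, j[m]] <- K[i, j[m]] + w[m]
  }
  K
}

# apply matrix M along dimension `dm` of array a
.apply_along <- function(a, M, dm) {
  d <- dim(a)
  perm <- c(dm, setdiff(seq_along(d), dm))
  ap <- aperm(a, perm)
  out <- M %*% matrix(ap, nrow = d[dm])
  out <- array(out, dim = d[perm])
  aperm(out, order(perm))
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing with per-axis sigma
#' `fwhm / (2 sqrt(2 log 2))` converted to voxel units. Boundary handling
#' is nearest-edge replication, so a constant volume passes through
#' unchanged and total intensity is conserved for inputs supported away
#' from the boundary. `fwhm_mm = 0` is the identity.
#'
#' @param vol3d 3D numeric array.
#' @param fwhm_mm kernel full width at half maximum, mm.
#' @param voxel_size_mm length-3 voxel edge lengths, mm.
#' @export
gaussian_smooth <- function(vol3d, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm < 0) stop("FWHM must be >= 0")
  if (fwhm_mm == 0) return(vol3d)
  stopifnot(length(dim(vol3d)) == 3L, length(voxel_size_mm) == 3L)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(vol3d)
  out <- vol3d
  for (ax in 1:3) out <- .apply_along(out, .gauss_matrix(d[ax], sig[ax]), ax)
  out
}

#' @rdname gaussian_smooth
#' @param vol a [ts_volume()]; each frame is smoothed independently.
#' @export
smooth_volume <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "ts_volume"))
  if (fwhm_mm < 0) stop("FWHM must be >= 0")
  if (fwhm_mm == 0) return(vol)
  d <- dim(vol$data)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_size_mm
  out <- vol$data
  for (ax in 1:3) out <- .apply_along(out, .gauss_matrix(d[ax], sig[ax]), ax)
  .ts_volume_fast(out, vol$tr_seconds, vol$voxel_size_mm, vol$affine)
}

#' Ideal spectral band-pass filter
#'
#' Discrete-Fourier realization: transform, zero every frequency bin with
#' |f| outside the closed interval \[low, high\], inverse-transform. A bin
#' at frequency f is in-band iff `low <= f <= high`; the identical rule is
#' used by the ALFF computations, so filter and spectrum are exactly
#' consistent. DC is always removed (low > 0 is required).
#'
#' @param x numeric vector or time-by-series matrix.
#' @param tr sampling interval, s.
#' @param low_hz,high_hz band edges; must satisfy
#'   `0 < low < high <= 1/(2 tr)`.
#' @export
bandpass <- function(x, tr, low_hz = 0.02, high_hz = 0.07) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  nyq <- 1 / (2 * tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz <= nyq + 1e-12))
    stop(sprintf("band [%g, %g] outside (0, Nyquist = %g]",
                 low_hz, high_hz, nyq), call. = FALSE)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) / (n * tr)   # |f| per bin
  keep <- f >= low_hz & f <= high_hz
  if (is.matrix(x)) {
    X <- stats::mvfft(x)
    X[!keep, ] <- 0
    Re(stats::mvfft(X, inverse = TRUE)) / n
  } else {
    X <- stats::fft(x)
    X[!keep] <- 0
    Re(stats::fft(X, inverse = TRUE)) / n
  }
}

#' Full per-subject preprocessing chain
#'
#' Fixed order: discard initial volumes, voxel-wise linear detrend,
#' Gaussian spatial smoothing. Band restriction is not applied here: the
#' spectral analysis (ALFF / f-ALFF) selects its own bands from the full
#' spectrum of the detrended, smoothed series. The steps applied are
#' recorded in the `"log"` attribute.
#'
#' @param vol raw [ts_volume()].
#' @param config a [preprocess_config()].
#' @export
preprocess_subject <- function(vol, config = preprocess_config()) {
  out <- discard_initial(vol, config$n_discard, config$n_keep)
  out <- detrend_volume(out)
  out <- smooth_volume(out, config$smooth_fwhm_mm)
  attr(out, "log") <- c(
    sprintf("discard_initial: dropped %d, kept %d", config$n_discard,
            config$n_keep),
    "detrend_linear: voxel-wise intercept+slope removal",
    sprintf("gaussian_smooth: fwhm %g mm", config$smooth_fwhm_mm))
  out
}
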