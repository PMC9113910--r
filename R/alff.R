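#' One-sided amplitude spectrum
#'
#' Amplitude convention: `a_k = (2/n) |DFT_k|` for interior bins
#' `0 < k < n/2`; the DC and (for even n) Nyquist bins are unhalved,
#' `a_k = |DFT_k| / n`. Under this convention a pure sinusoid of amplitude
#' `a` at an exact interior bin frequency has spectral amplitude `a` at
#' that bin, and the per-bin powers `a_k^2 / 2` (interior) and `a_k^2`
#' (DC/Nyquist) satisfy Parseval: their sum over k >= 1 plus the squared
#' mean equals the series mean square.
#'
#' @param x numeric series, length >= 8, no NAs (detrended upstream).
#' @param tr sampling interval in seconds.
#' @return list with `frequencies_hz` (0..Nyquist, ascending), `amplitude`
#'   (nonnegative, length `floor(n/2) + 1`), and `power` per bin.
#' @export
periodogram <- function(x, tr) {
  if (anyNA(x) || !all(is.finite(x))) stop("series contains NA/non-finite")
  n <- length(x)
  if (n < 8L) stop("series too short for a spectrum (need n >= 8)")
  amp <- .amp_matrix(matrix(x, ncol = 1))[, 1]
  nk <- length(amp)
  k <- 0:(nk - 1)
  interior <- k > 0 & k < n / 2
  pow <- ifelse(interior, amp^2 / 2, amp^2)
  list(frequencies_hz = k / (n * tr), amplitude = amp, power = pow)
}

# amplitude spectra for all columns of a time-by-series matrix
.amp_matrix <- function(mat) {
  n <- nrow(mat)
  nk <- floor(n / 2) + 1L
  A <- Mod(stats::mvfft(mat))[seq_len(nk), , drop = FALSE] / n
  k <- 0:(nk - 1)
  interior <- k > 0 & k < n / 2
  A[interior, ] <- 2 * A[interior, , drop = FALSE]
  A
}

# indices of spectrum bins with low <= f <= high (closed interval)
.band_bins <- function(frequencies_hz, low, high) {
  which(frequencies_hz >= low - 1e-12 & frequencies_hz <= high + 1e-12)
}

#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' Mean spectral amplitude over the bins whose frequency lies in the
#' closed band \[low, high\]. Amplitude (square root of power) is the
#' field's standard ALFF convention; set `power = TRUE` to average squared
#' amplitude instead.
#'
#' @param spec a [periodogram()].
#' @param band length-2 band edges in Hz (default 0.02-0.07).
#' @param power use squared amplitude.
#' @export
compute_alff <- function(spec, band = c(0.02, 0.07), power = FALSE) {
  idx <- .band_bins(spec$frequencies_hz, band[1], band[2])
  if (!length(idx)) stop("no spectrum bins inside the band")
  a <- spec$amplitude[idx]
  if (power) mean(a^2) else mean(a)
}

#' Fractional ALFF (f-ALFF)
#'
#' Sum of in-band amplitude divided by the amplitude summed over the total
#' band (DC excluded, upper edge included): the fraction of spontaneous
#' fluctuation amplitude that lies in the low-frequency band. Always in
#' \[0, 1\]; 0 when the denominator vanishes.
#'
#' @param spec a [periodogram()].
#' @param band low-frequency band, Hz.
#' @param total_band total band, Hz; must contain `band`. The default
#'   upper edge 0.25 Hz is the Nyquist frequency at TR = 2 s.
#' @param power use squared amplitude in numerator and denominator.
#' @export
compute_falff <- function(spec, band = c(0.02, 0.07),
                          total_band = c(0, 0.25), power = FALSE) {
  if (band[1] < total_band[1] - 1e-12 || band[2] > total_band[2] + 1e-12)
    stop("band must be contained in total_band")
  f <- spec$frequencies_hz
  num_idx <- .band_bins(f, band[1], band[2])
  den_idx <- which(f > 1e-15 & f <= total_band[2] + 1e-12)  # DC excluded
  a <- spec$amplitude
  if (power) a <- a^2
  den <- sum(a[den_idx])
  if (den == 0) return(0)
  sum(a[num_idx]) / den
}

#' Voxel-wise ALFF / f-ALFF maps for one subject
#'
#' Applies the spectral ALFF and f-ALFF definitions to every in-mask voxel
#' of a preprocessed volume. f-ALFF is computed from the full (unfiltered)
#' spectrum of the detrended series, since band-limiting the series first
#' would make numerator and denominator identical.
#'
#' @param vol preprocessed [ts_volume()].
#' @param mask 3D logical array, same spatial shape.
#' @param band low-frequency band in Hz.
#' @param total_band total band in Hz for the f-ALFF denominator.
#' @return list with `alff` and `falff` [stat_map()]s.
#' @export
map_subject <- function(vol, mask, band = c(0.02, 0.07),
                        total_band = c(0, 0.25)) {
  stopifnot(inherits(vol, "ts_volume"))
  d <- dim(vol$data)
  if (!identical(dim(mask), d[1:3])) stop("mask/volume shape mismatch")
  nt <- d[4]
  mat <- vol$data
  dim(mat) <- c(prod(d[1:3]), nt)
  mat <- mat[as.vector(mask), , drop = FALSE]
  A <- .amp_matrix(t(mat))                        # bins x voxels
  f <- (0:(nrow(A) - 1)) / (nt * vol$tr_seconds)
  num_idx <- .band_bins(f, band[1], band[2])
  if (!length(num_idx)) stop("no spectrum bins inside the band")
  den_idx <- which(f > 1e-15 & f <= total_band[2] + 1e-12)
  alff_v <- colMeans(A[num_idx, , drop = FALSE])
  den <- colSums(A[den_idx, , drop = FALSE])
  falff_v <- ifelse(den == 0, 0, colSums(A[num_idx, , drop = FALSE]) / den)
  alff_arr <- array(NA_real_, d[1:3]); alff_arr[mask] <- alff_v
  falff_arr <- array(NA_real_, d[1:3]); falff_arr[mask] <- falff_v
  list(alff = stat_map(alff_arr, "alff", mask, vol$affine),
       falff = stat_map(falff_arr, "falff", mask, vol$affine))
}

#' Standardize a map for group comparison
#'
#' `divide_by_global_mean` divides by the in-mask mean (mALFF-style; the
#' in-mask mean of the output is exactly 1). `zscore` centres and scales
#' to unit in-mask standard deviation.
#'
#' @param map a [stat_map()].
#' @param mode `"divide_by_global_mean"` or `"zscore"`.
#' @export
standardize_map <- function(map, mode = c("divide_by_global_mean", "zscore")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "stat_map"))
  v <- map$data[map$mask]
  out <- map$data
  if (mode == "divide_by_global_mean") {
    g <- mean(v)
    if (g == 0) stop("global mean is zero; cannot divide")
    out[map$mask] <- v / g
    kind <- switch(map$kind, alff = "malff", falff = "mfalff", map$kind)
  } else {
    s <- stats::sd(v)
    if (s == 0) s <- 1
    out[map$mask] <- (v - mean(v)) / s
    kind <- map$kind   # standardized field keeps its kind tag
  }
  m <- map
  m$data <- out
  m$kind <- kind
  m
}
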