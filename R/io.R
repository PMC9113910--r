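#' Construct a 4D BOLD time-series volume
#'
#' The raw unit of analysis: a 4D array of BOLD intensities (x, y, z, t)
#' together with its repetition time, voxel size and voxel-to-world affine.
#'
#' @param data 4D numeric array (x, y, z, t); all values must be finite.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param voxel_size_mm length-3 numeric vector of voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform; defaults to a diagonal
#'   scaling by `voxel_size_mm` (RAS+, 0-based voxel indices).
#' @return an object of class `ts_volume`.
#' @export
ts_volume <- function(data, tr_seconds,
                      voxel_size_mm = c(3.4375, 3.4375, 5.2),
                      affine = NULL) {
  if (length(dim(data)) != 4L)
    stop("time-series volume must be 4-dimensional, got ",
         length(dim(data)), "D", call. = FALSE)
  if (dim(data)[4] < 1L) stop("t dimension must have length >= 1")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a single positive number")
  if (!all(is.finite(data))) stop("volume contains non-finite intensities")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive values")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  stopifnot(all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, tr_seconds = tr_seconds,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine),
            class = "ts_volume")
}

# internal constructor skipping the finiteness scan (hot paths whose
# inputs are already validated)
.ts_volume_fast <- function(data, tr_seconds, voxel_size_mm, affine = NULL) {
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  structure(list(data = data, tr_seconds = tr_seconds,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine),
            class = "ts_volume")
}

#' @export
print.ts_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_volume> %dx%dx%d grid, %d timepoints, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' Construct a statistic map
#'
#' A 3D scalar field (ALFF, f-ALFF, t or p values) aligned to a brain mask.
#' Voxels outside the mask are stored as `NA`.
#'
#' @param data 3D numeric array.
#' @param kind one of `"alff"`, `"falff"`, `"malff"`, `"mfalff"`, `"t"`, `"p"`.
#' @param mask 3D logical array of the same shape.
#' @param affine 4x4 voxel-to-world transform.
#' @export
stat_map <- function(data, kind, mask, affine = diag(4)) {
  kind <- match.arg(kind, c("alff", "falff", "malff", "mfalff", "t", "p"))
  if (length(dim(data)) != 3L) stop("stat map data must be 3D")
  if (!identical(dim(data), dim(mask)))
    stop("map and mask shapes differ")
  if (!any(mask)) stop("mask has no voxels")
  data[!mask] <- NA_real_
  v <- data[mask]
  if (kind %in% c("alff", "falff", "malff", "mfalff") && any(v < 0, na.rm = TRUE))
    stop(kind, " values must be nonnegative")
  if (kind == "falff" && any(v > 1 + 1e-12, na.rm = TRUE))
    stop("falff values must be <= 1")
  structure(list(data = data, kind = kind, mask = mask, affine = affine),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map:%s> %s grid, %d in-mask voxels\n", x$kind,
              paste(dim(x$data), collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' In-mask values of a statistic map
#' @param map a `stat_map`.
#' @return numeric vector of in-mask voxel values.
#' @export
map_values <- function(map) map$data[map$mask]

# --- NIfTI I/O -------------------------------------------------------------

# Time-unit handling: RNifti reports pixel units; TR stored in ms or us is
# converted to seconds on read.
.tr_from_header <- function(img) {
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4L) pd[4] else 0
  un <- tryCatch(RNifti::pixunits(img), error = function(e) character())
  if ("ms" %in% un) tr <- tr / 1000
  if ("us" %in% un) tr <- tr / 1e6
  tr
}

#' Read a 4D NIfTI time series
#'
#' @param path path to a NIfTI-1 file with 4 dimensions.
#' @return a [ts_volume()]; TR is taken from the header (converted to
#'   seconds when stored in ms/us) and the affine is preserved.
#' @export
read_timeseries <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("expected a 4D NIfTI time series, got ",
         length(dim(img)), "D: ", path, call. = FALSE)
  pd <- RNifti::pixdim(img)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  tr <- .tr_from_header(img)
  if (!is.finite(tr) || tr <= 0) tr <- 1
  ts_volume(array(as.numeric(img), dim = dim(img)), tr_seconds = tr,
            voxel_size_mm = pd[1:3], affine = matrix(aff, 4, 4))
}

.as_nifti <- function(arr, voxel_size_mm, tr_seconds = NULL) {
  img <- RNifti::asNifti(arr)
  pd <- voxel_size_mm
  if (!is.null(tr_seconds)) pd <- c(pd, tr_seconds)
  RNifti::`pixdim<-`(img, pd)
}

#' Write a time series, mask, atlas or statistic map as NIfTI
#'
#' `write_timeseries()` stores the TR in the header (seconds);
#' `write_map()` stores in-mask values with 0 outside the mask;
#' `write_mask()`/`write_atlas()` store integer grids.
#'
#' @param vol,map,mask,atlas object to write.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel edge lengths stored in the header (masks and
#'   atlases carry no affine of their own).
#' @name nifti-write
#' @export
write_timeseries <- function(vol, path) {
  stopifnot(inherits(vol, "ts_volume"))
  img <- .as_nifti(vol$data, vol$voxel_size_mm, vol$tr_seconds)
  img <- RNifti::`pixunits<-`(img, c("mm", "s"))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti-write
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  if (!identical(dim(map$data), dim(map$mask)))
    stop("map/mask shape mismatch")
  out <- map$data
  out[!map$mask] <- 0
  vx <- .affine_voxdim(map$affine)
  RNifti::writeNifti(.as_nifti(out, vx), path)
  invisible(path)
}

.affine_voxdim <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' Read a statistic map written by [write_map()]
#' @param path NIfTI path.
#' @param kind map kind tag.
#' @param mask 3D logical mask to apply.
#' @export
read_map <- function(path, kind, mask) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI map")
  if (!identical(dim(img), dim(mask))) stop("map/mask shape mismatch")
  aff <- matrix(RNifti::xform(img), 4, 4)
  stat_map(array(as.numeric(img), dim = dim(img)), kind, mask, aff)
}

#' @rdname nifti-write
#' @export
write_mask <- function(mask, path, voxel_size_mm = c(3.4375, 3.4375, 5.2)) {
  RNifti::writeNifti(.as_nifti(array(as.integer(mask), dim = dim(mask)),
                               voxel_size_mm), path)
  invisible(path)
}

#' Read a 3D brain mask (nonzero = inside)
#' @param path NIfTI path.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("mask must be 3D")
  m <- array(as.numeric(img) != 0, dim = dim(img))
  if (!any(m)) stop("mask has no nonzero voxels")
  m
}

#' @rdname nifti-write
#' @export
write_atlas <- function(atlas, path, voxel_size_mm = c(3.4375, 3.4375, 5.2)) {
  stopifnot(is.list(atlas), !is.null(atlas$data))
  RNifti::writeNifti(.as_nifti(array(as.integer(atlas$data),
                                     dim = dim(atlas$data)),
                               voxel_size_mm), path)
  nm <- data.frame(label = as.integer(names(atlas$names)),
                   name = unname(unlist(atlas$names)))
  utils::write.csv(nm, .atlas_names_path(path), row.names = FALSE)
  invisible(path)
}

.atlas_names_path <- function(path) sub("\\.nii(\\.gz)?$", "_labels.csv", path)

#' Construct / read an integer-labelled region atlas
#'
#' An atlas is an integer 3D grid (0 = background) plus a label->name map.
#' Every nonzero label in the grid must have a name.
#'
#' @param data 3D integer array.
#' @param names named list or vector, names are label integers.
#' @export
label_atlas <- function(data, names) {
  if (length(dim(data)) != 3L) stop("atlas grid must be 3D")
  if (any(data < 0)) stop("atlas labels must be nonnegative")
  labs <- sort(unique(as.integer(data[data != 0])))
  nm <- as.list(names)
  missing <- setdiff(labs, as.integer(base::names(nm)))
  if (length(missing))
    stop("atlas labels missing from names map: ",
         paste(missing, collapse = ", "))
  structure(list(data = array(as.integer(data), dim = dim(data)), names = nm),
            class = "label_atlas")
}

#' @rdname label_atlas
#' @param path NIfTI path; region names are read from the `_labels.csv`
#'   sidecar written by [write_atlas()].
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("atlas must be 3D")
  nm <- utils::read.csv(.atlas_names_path(path))
  names_list <- as.list(as.character(nm$name))
  base::names(names_list) <- nm$label
  label_atlas(array(as.integer(img), dim = dim(img)), names_list)
}

# --- clinical tables -------------------------------------------------------

.clinical_cols <- c("subject_id", "group", "vas_baseline",
                    paste0("vas_week", 1:4), paste0("sleep_week", 1:4))

#' Validate a clinical follow-up table
#'
#' Checks the schema used throughout the package: per-subject group label
#' (`treatment`/`control`), VAS (0-10 points) at baseline and weeks 1-4,
#' continuous sleep hours at weeks 1-4. Missing values are not permitted.
#'
#' @param df data.frame to validate.
#' @return the validated data.frame (invisibly usable), group as factor.
#' @export
validate_clinical_table <- function(df) {
  missing <- setdiff(.clinical_cols, names(df))
  if (length(missing))
    stop("clinical table missing columns: ", paste(missing, collapse = ", "))
  if (anyNA(df[.clinical_cols])) stop("clinical table contains missing values")
  if (!all(df$group %in% c("treatment", "control")))
    stop("group must be 'treatment' or 'control'")
  vas <- as.matrix(df[c("vas_baseline", paste0("vas_week", 1:4))])
  if (any(vas < 0 | vas > 10))
    stop("VAS values must lie in [0, 10]")
  slp <- as.matrix(df[paste0("sleep_week", 1:4)])
  if (any(slp < 0)) stop("sleep hours must be >= 0")
  df$group <- factor(df$group, levels = c("treatment", "control"))
  df
}

#' Read / write a clinical table as CSV
#' @param path CSV path with a header row.
#' @export
read_clinical_table <- function(path) {
  validate_clinical_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_clinical_table
#' @param df clinical data.frame (validated before writing).
#' @export
write_clinical_table <- function(df, path) {
  df <- validate_clinical_table(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a cluster table as CSV
#' @param tab cluster table (see [cluster_threshold()]).
#' @param path CSV path.
#' @export
write_cluster_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a YAML pipeline configuration
#'
#' Thin wrapper used by the analysis drivers; returns the YAML document as
#' a nested list. Requires the `yaml` package.
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  yaml::read_yaml(path)
}
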