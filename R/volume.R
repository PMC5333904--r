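#' Tissue label codes
#'
#' Integer codes used throughout the package for hard three-class tissue
#' segmentations of skull-stripped brain volumes: 0 background, 1 CSF,
#' 2 grey matter, 3 white matter.
#'
#' @format Named integer vector.
#' @export
TISSUE_CODES <- c(background = 0L, csf = 1L, gm = 2L, wm = 3L)

#' Construct an intensity volume
#'
#' A 3D scalar image on a fixed voxel grid with a declared intensity range.
#' Values are kept as doubles internally; the nominal 12-bit 0--4095 scale of
#' MP2RAGE-style uniform images is a convention of the data, not a storage
#' format, because standardisation transforms produce non-integer outputs.
#'
#' @param data 3D numeric array, all values finite.
#' @param intensity_min,intensity_max Declared intensity range (defaults 0 and
#'   4095). `intensity_min < intensity_max` is required.
#' @param voxel_size Voxel edge lengths in mm (length-3, default 0.7 mm
#'   isotropic).
#' @return An object of class `intensity_volume` with fields `data`,
#'   `intensity_min`, `intensity_max`, `voxel_size`.
#' @export
intensity_volume <- function(data, intensity_min = 0, intensity_max = 4095,
                             voxel_size = c(0.7, 0.7, 0.7)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  if (!is.numeric(data))
    stop("`data` must be numeric (scalar voxel values)")
  if (anyNA(data) || any(!is.finite(data)))
    stop("`data` contains non-finite values")
  if (intensity_min >= intensity_max)
    stop("intensity_min must be < intensity_max")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)")
  structure(
    list(data = data, intensity_min = intensity_min,
         intensity_max = intensity_max, voxel_size = voxel_size),
    class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume> %s voxels @ %.3g x %.3g x %.3g mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = " x "),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$intensity_min, x$intensity_max))
  cat(sprintf("  data: min %.1f, max %.1f, %d non-zero voxels\n",
              min(x$data), max(x$data), sum(x$data != 0)))
  invisible(x)
}

#' Construct a tissue label map
#'
#' Hard three-class segmentation on the same grid as a companion volume.
#'
#' @param labels 3D integer array with codes 0 (background), 1 (CSF),
#'   2 (GM), 3 (WM) only.
#' @param voxel_size Voxel edge lengths in mm.
#' @return Object of class `tissue_label_map`.
#' @seealso [TISSUE_CODES]
#' @export
tissue_label_map <- function(labels, voxel_size = c(0.7, 0.7, 0.7)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), TISSUE_CODES)
  if (length(bad))
    stop("labels contain codes outside {0,1,2,3}: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size)),
            class = "tissue_label_map")
}

#' Construct a region-of-interest mask
#'
#' @param mask 3D logical array; must select at least one voxel.
#' @param tissue `"gm"` or `"wm"`: the tissue the ROI is meant to contain.
#' @param voxel_size Voxel edge lengths in mm.
#' @return Object of class `roi_mask` with a `voxel_count` field.
#' @export
roi_mask <- function(mask, tissue = c("gm", "wm"), voxel_size = c(0.7, 0.7, 0.7)) {
  tissue <- match.arg(tissue)
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("`mask` must be a 3D logical array")
  n <- sum(mask)
  if (n == 0L) stop("ROI mask selects no voxels")
  structure(list(mask = mask, tissue = tissue, voxel_count = n,
                 voxel_size = as.numeric(voxel_size)),
            class = "roi_mask")
}

grid_shape <- function(x) {
  if (inherits(x, "intensity_volume")) dim(x$data)
  else if (inherits(x, "tissue_label_map")) dim(x$labels)
  else if (inherits(x, "roi_mask")) dim(x$mask)
  else if (is.array(x)) dim(x)
  else stop("cannot determine grid shape of a ", class(x)[1])
}

grid_voxel_size <- function(x) {
  if (is.list(x) && !is.null(x$voxel_size)) x$voxel_size else c(NA_real_, NA_real_, NA_real_)
}

#' Check that two gridded objects share one voxel grid
#'
#' Registration is out of scope for this package: every multi-image operation
#' requires its inputs to live on the same grid, and this is the predicate
#' they use. Shapes must match exactly and voxel sizes within `tol` mm.
#'
#' @param a,b Volumes, label maps or ROI masks.
#' @param tol Voxel-size tolerance in mm (default 1e-6).
#' @return `TRUE` or `FALSE`.
#' @export
check_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(as.integer(grid_shape(a)), as.integer(grid_shape(b))))
    return(FALSE)
  va <- grid_voxel_size(a); vb <- grid_voxel_size(b)
  if (anyNA(va) || anyNA(vb)) return(TRUE)  # no size metadata: shapes suffice
  all(abs(va - vb) < tol)
}

assert_same_grid <- function(a, b, what = "inputs") {
  if (!check_same_grid(a, b))
    stop(what, " are not on the same voxel grid (shape/voxel size mismatch)")
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D scalar NIfTI-1 image (`.nii` or `.nii.gz`). Values outside the
#' declared intensity range are reported with a warning but never silently
#' clipped.
#'
#' @param path Path to an existing NIfTI-1 file.
#' @param intensity_min,intensity_max Declared intensity range for the dataset
#'   (defaults 0 and 4095).
#' @return An [intensity_volume()].
#' @export
read_volume <- function(path, intensity_min = 0, intensity_max = 4095) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d)) d <- length(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L]
    d <- dim(img)
  }
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))  # singleton dims dropped by NIfTI
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), " dimensions: ", path)
  vox <- RNifti::pixdim(img)[seq_len(3)]
  vox[is.na(vox) | vox <= 0] <- 1
  data <- as.vector(img)
  attributes(data) <- list(dim = d)
  storage.mode(data) <- "double"
  n_out <- sum(data < intensity_min | data > intensity_max)
  if (n_out > 0)
    warning(n_out, " voxels outside declared intensity range [",
            intensity_min, ", ", intensity_max, "]")
  intensity_volume(data, intensity_min, intensity_max, voxel_size = vox)
}

#' Write a volume to NIfTI-1
#'
#' Lossless float64 write by default; with `quantize = TRUE` values are rounded
#' to the nearest integer and clamped to the declared range before writing
#' (the convention of 12-bit integer datasets).
#'
#' @param vol An [intensity_volume()].
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @param quantize Round and clamp to the declared integer scale.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, quantize = FALSE) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  data <- vol$data
  if (quantize)
    data <- pmin(pmax(round(data), vol$intensity_min), vol$intensity_max)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path, datatype = if (quantize) "int16" else "double")
  invisible(path)
}

#' Read a tissue label map from NIfTI-1
#'
#' @param path NIfTI-1 file with integer codes 0--3.
#' @return A [tissue_label_map()].
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D label map: ", path)
  vox <- RNifti::pixdim(img)[seq_len(3)]
  lab <- as.array(img)
  attributes(lab) <- list(dim = dim(img))
  tissue_label_map(round(lab), voxel_size = vox)
}

#' Write a tissue label map to NIfTI-1
#' @param labels A [tissue_label_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "tissue_label_map"))
  img <- RNifti::asNifti(labels$labels)
  RNifti::pixdim(img) <- labels$voxel_size
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
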