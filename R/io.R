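# NIfTI-1 reading and writing, via RNifti.  Volumes are written as float32,
# ROI label maps as uint16, binary masks as uint8.  Spacing is carried in
# pixdim and geometry in an axis-aligned qform/sform pair.

nifti_with_geometry <- function(arr, spacing, origin, datatype) {
  img <- RNifti::asNifti(structure(arr, pixdim = spacing,
                                   pixunits = c("mm", "s")),
                         datatype = datatype)
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::`sform<-`(img, structure(m, code = 2L))
}

read_geometry <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  x <- RNifti::xform(img)
  sp <- RNifti::pixdim(img)
  list(spacing = as.numeric(sp[1:3]),
       origin = as.numeric(x[1:3, 4]),
       dim = dim(img))
}

check_scalar_3d <- function(img, path) {
  d <- dim(img)
  if (length(d) != 3)
    stop_petsac(fmt("'%s' is %d-dimensional; a scalar 3D image is required",
                    path, length(d)), "petsac_format_error")
  invisible(TRUE)
}

#' Read a PET volume from a NIfTI file
#'
#' @param path path to a scalar 3D NIfTI image (`.nii` or `.nii.gz`) holding
#'   SUV (or activity-concentration) values.
#' @return A [pet_volume]; spacing and origin are taken from the header and
#'   values are cast to double.
#' @seealso [save_volume()]
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop_petsac(fmt("file not found: '%s'", path), "petsac_io_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_petsac(
                    fmt("cannot read '%s' as NIfTI: %s", path, conditionMessage(e)),
                    "petsac_format_error"))
  check_scalar_3d(img, path)
  g <- read_geometry(img)
  pet_volume(array(as.numeric(img), dim = dim(img)), g$spacing, g$origin)
}

#' Write a PET volume to a NIfTI file
#'
#' Voxels are stored as float32, so a save/load round trip reproduces values
#' to float32 precision.
#'
#' @param volume a [pet_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- nifti_with_geometry(volume$values, volume$spacing, volume$origin,
                             "float")
  tryCatch(RNifti::writeNifti(img, path, datatype = "float"),
           error = function(e) stop_petsac(
             fmt("cannot write '%s': %s", path, conditionMessage(e)),
             "petsac_io_error"))
  invisible(path)
}

#' Read an ROI label map from a NIfTI file
#'
#' @param path path to a scalar 3D integer NIfTI label image (0 = background,
#'   1..K = ROIs).
#' @return An [roi_set].
#' @export
load_rois <- function(path) {
  if (!file.exists(path))
    stop_petsac(fmt("file not found: '%s'", path), "petsac_io_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_petsac(
                    fmt("cannot read '%s' as NIfTI: %s", path, conditionMessage(e)),
                    "petsac_format_error"))
  check_scalar_3d(img, path)
  g <- read_geometry(img)
  roi_set(array(as.integer(img), dim = dim(img)), g$spacing, g$origin)
}

#' Write an ROI label map to a NIfTI file
#'
#' Labels are stored as uint16; the round trip is exact.
#'
#' @param rois an [roi_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  img <- nifti_with_geometry(rois$labels, rois$spacing, rois$origin, "uint16")
  tryCatch(RNifti::writeNifti(img, path, datatype = "uint16"),
           error = function(e) stop_petsac(
             fmt("cannot write '%s': %s", path, conditionMessage(e)),
             "petsac_io_error"))
  invisible(path)
}

#' Write a binary segmentation mask to a NIfTI file
#'
#' Voxels are stored as uint8 (0/1); the round trip is exact.  The per-ROI
#' decomposition and any SAC branch decisions are not stored in the NIfTI
#' itself; use [write_mask_sidecar()] for that.
#'
#' @param mask a [segmentation_mask] (or a logical 3D array plus explicit
#'   `spacing`/`origin`).
#' @param path output path.
#' @param spacing,origin grid geometry; taken from `mask` when it is a
#'   `segmentation_mask`.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path, spacing = NULL, origin = NULL) {
  if (inherits(mask, "segmentation_mask")) {
    arr <- mask$mask; spacing <- mask$spacing; origin <- mask$origin
  } else {
    arr <- mask
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (is.null(origin)) origin <- c(0, 0, 0)
  }
  storage.mode(arr) <- "integer"
  img <- nifti_with_geometry(arr, spacing, origin, "uint8")
  tryCatch(RNifti::writeNifti(img, path, datatype = "uint8"),
           error = function(e) stop_petsac(
             fmt("cannot write '%s': %s", path, conditionMessage(e)),
             "petsac_io_error"))
  invisible(path)
}

#' Read a binary mask written by [save_mask()]
#'
#' @param path path to a uint8 NIfTI mask.
#' @return A list with `mask` (logical 3D array), `spacing`, `origin`.
#' @export
load_mask <- function(path) {
  if (!file.exists(path))
    stop_petsac(fmt("file not found: '%s'", path), "petsac_io_error")
  img <- RNifti::readNifti(path)
  check_scalar_3d(img, path)
  g <- read_geometry(img)
  list(mask = array(as.integer(img) != 0, dim = dim(img)),
       spacing = g$spacing, origin = g$origin)
}
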