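# Binary morphology on 3D masks by neighbor shifting.  Used for ROI
# construction (ground-truth dilation), observer perturbation, and surface
# voxel extraction.  One step with the 6-neighborhood grows a diamond
# (octahedral) ball; the 26-neighborhood grows a cube.

#' Dilate or erode a binary 3D mask
#'
#' `steps` iterations of binary dilation (or erosion) with the structuring
#' element implied by `connectivity`: 6 = face neighbors (diamond growth),
#' 26 = full 3x3x3 box.
#'
#' @param mask logical 3D array.
#' @param steps number of iterations (>= 0; 0 returns the input).
#' @param connectivity 6, 18 or 26.
#' @return Logical 3D array of the same shape.
#' @export
dilate_mask <- function(mask, steps = 1, connectivity = 6) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, steps >= 0)
  mask <- mask != 0
  if (steps == 0) return(mask)
  offs <- neighbor_offsets(connectivity)
  for (s in seq_len(steps)) {
    out <- mask
    for (i in seq_len(nrow(offs)))
      out <- out | shift3d(mask, offs[i, 1], offs[i, 2], offs[i, 3],
                           fill = FALSE)
    mask <- out
  }
  mask
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, steps = 1, connectivity = 6) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, steps >= 0)
  mask <- mask != 0
  if (steps == 0) return(mask)
  offs <- neighbor_offsets(connectivity)
  for (s in seq_len(steps)) {
    out <- mask
    for (i in seq_len(nrow(offs)))
      out <- out & shift3d(mask, offs[i, 1], offs[i, 2], offs[i, 3],
                           fill = FALSE)
    mask <- out
  }
  mask
}

# voxels of `mask` with at least one face neighbor outside the mask
surface_voxels <- function(mask) {
  mask <- mask != 0
  mask & !erode_mask(mask, 1, connectivity = 6)
}
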