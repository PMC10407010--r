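# Volume, surface and shape features.  Surface area is the digital surface:
# the summed area of exposed voxel faces.  This makes the cube identities
# exact (a cube of side s has area 6 s^2, hence sphericity (pi/6)^(1/3));
# for smooth blobs the digital surface overestimates the geometric surface
# by a factor approaching 3/2, so sphericity is a relative shape index
# across lesions, not an absolute geometric one.

#' Metabolic tumor volume (MTV)
#'
#' Voxel count times physical voxel volume, in cm^3.  An empty mask has
#' MTV 0.
#'
#' @param mask binary 3D array or `segmentation_mask`.
#' @param spacing voxel size in mm per axis (taken from `mask` when it is a
#'   `segmentation_mask`).
#' @return MTV in cm^3.
#' @examples
#' mtv(array(c(rep(TRUE, 10), rep(FALSE, 17)), c(3, 3, 3)),
#'     spacing = c(2, 2, 2))  # 0.08
#' @export
mtv <- function(mask, spacing = NULL) {
  if (inherits(mask, "segmentation_mask")) {
    spacing <- mask$spacing; mask <- mask$mask
  }
  if (is.null(spacing))
    stop_petsac("'spacing' is required for a bare mask array",
                "petsac_format_error")
  sum(mask != 0) * prod(spacing) / 1000
}

#' Total lesion glycolysis (TLG)
#'
#' `TLG = MTV x SUVmean` over the same mask, in cm^3 (SUV-weighted).  An
#' empty mask yields 0 with a warning.
#'
#' @param volume a [pet_volume].
#' @param mask binary 3D array or `segmentation_mask`.
#' @param spacing voxel size in mm (defaults to the volume's).
#' @return TLG in cm^3.
#' @export
tlg <- function(volume, mask, spacing = NULL) {
  if (inherits(mask, "segmentation_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    mask <- mask$mask
  }
  if (is.null(spacing)) spacing <- volume$spacing
  m <- as_mask_array(mask)
  if (!any(m)) {
    warning("empty mask: TLG = 0", call. = FALSE)
    return(0)
  }
  mtv(m, spacing) * mean(volume$values[m])
}

# physical (mm) coordinates of mask voxel centers, n x 3
voxel_coords <- function(mask, spacing, origin = c(0, 0, 0)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

# exposed-face count of a binary mask, weighted by per-face physical area
digital_surface_area <- function(mask, spacing) {
  mask <- mask != 0
  face_area <- c(spacing[2] * spacing[3],   # faces normal to x
                 spacing[1] * spacing[3],   # normal to y
                 spacing[1] * spacing[2])   # normal to z
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  total <- 0
  for (ax in 1:3) {
    o <- axes[[ax]]
    for (sgn in c(-1, 1)) {
      nb <- shift3d(mask, sgn * o[1], sgn * o[2], sgn * o[3], fill = FALSE)
      total <- total + sum(mask & !nb) * face_area[ax]
    }
  }
  total
}

#' Geometric (shape) features of a lesion
#'
#' Shape descriptors from the binary mask and voxel geometry:
#' * `surface_area_mm2`: digital (exposed voxel face) surface area;
#' * `surface_to_volume`: surface area / volume, in 1/mm;
#' * `sphericity`: `pi^(1/3) (6 V)^(2/3) / A`; with the digital-surface
#'   convention a cube of voxels scores exactly `(pi/6)^(1/3)` (about
#'   0.806) and a digitized ball tends to `2/3` (see the vignette);
#' * `compactness1` = `V / (sqrt(pi) A^(3/2))`, `compactness2` =
#'   `36 pi V^2 / A^3`;
#' * `spherical_disproportion`: `A / (4 pi R^2)` with `R = (3V / 4 pi)^(1/3)`;
#' * `max_diameter_mm`: largest pairwise distance between surface voxel
#'   centers.
#'
#' @param mask binary 3D array or `segmentation_mask`; non-empty.
#' @param spacing voxel size in mm.
#' @return Named numeric vector of the 7 features (volumes in mm^3 inside
#'   the formulas; `mtv()` reports cm^3 separately).
#' @export
geometric_features <- function(mask, spacing = NULL) {
  if (inherits(mask, "segmentation_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    mask <- mask$mask
  }
  if (is.null(spacing))
    stop_petsac("'spacing' is required for a bare mask array",
                "petsac_format_error")
  mask <- mask != 0
  if (!any(mask))
    stop_petsac("empty mask: no voxels to quantify", "petsac_empty_error")
  v_mm3 <- sum(mask) * prod(spacing)
  a_mm2 <- digital_surface_area(mask, spacing)
  r_eq <- (3 * v_mm3 / (4 * pi))^(1 / 3)
  surf <- surface_voxels(mask)
  xyz <- voxel_coords(surf, spacing)
  maxd <- if (nrow(xyz) > 1) sqrt(max(dist2_all(xyz))) else 0
  c(surface_area_mm2 = a_mm2,
    surface_to_volume = a_mm2 / v_mm3,
    sphericity = pi^(1 / 3) * (6 * v_mm3)^(2 / 3) / a_mm2,
    compactness1 = v_mm3 / (sqrt(pi) * a_mm2^1.5),
    compactness2 = 36 * pi * v_mm3^2 / a_mm2^3,
    spherical_disproportion = a_mm2 / (4 * pi * r_eq^2),
    max_diameter_mm = maxd)
}

# all squared pairwise distances between rows of an n x 3 matrix
dist2_all <- function(xyz) {
  g <- tcrossprod(xyz)
  n2 <- diag(g)
  outer(n2, n2, "+") - 2 * g
}
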