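# Dissemination features: scalar summaries of how far apart a patient's
# disconnected lesions lie.  All distances are between voxel-center
# positions in physical mm; lesion centroids are unweighted voxel-center
# means, while the burden centroid is the MTV-weighted mean of the lesion
# centroids.  The exact composition of published dissemination panels
# varies; this set of 8 is a documented, literature-consistent choice (see
# the vignette).

#' Dissemination features of a patient's lesion set
#'
#' Eight features describing the spatial spread of the disconnected lesions:
#' `n_lesions`; `dmax_patient_mm` (largest pairwise centroid distance);
#' `dmax_bulk_mm` (largest distance from the highest-TLG lesion's centroid
#' to any other centroid); `mean_centroid_dist_mm` and
#' `sd_centroid_dist_mm` (mean / SD of all pairwise centroid distances);
#' `max_surface_dist_mm` (largest distance between surface voxels of two
#' different lesions); `mtv_dispersion_cm3` (SD of the per-lesion MTVs);
#' `burden_spread_mm` (mean distance of lesion centroids from the
#' MTV-weighted burden centroid).  With a single lesion every distance
#' feature is 0 and the count is 1.
#'
#' @param lesions a `lesion_set` (see [label_lesions()]).
#' @param volume the [pet_volume] the lesions were segmented on (needed to
#'   rank lesions by TLG).
#' @return Named numeric vector of 8 features.
#' @export
dissemination_features <- function(lesions, volume) {
  stopifnot(inherits(lesions, "lesion_set"))
  assert_aligned(lesions, volume, "lesion set and volume")
  nl <- n_lesions(lesions)
  if (nl == 0)
    stop_petsac("no lesions to quantify", "petsac_empty_error")
  spacing <- lesions$spacing

  cent <- matrix(0, nl, 3)
  mtvs <- numeric(nl)
  tlgs <- numeric(nl)
  for (j in seq_len(nl)) {
    m <- lesions$labels == j
    xyz <- voxel_coords(m, spacing, lesions$origin)
    cent[j, ] <- colMeans(xyz)
    mtvs[j] <- mtv(m, spacing)
    tlgs[j] <- mtvs[j] * mean(volume$values[m])
  }

  if (nl == 1) {
    return(c(n_lesions = 1, dmax_patient_mm = 0, dmax_bulk_mm = 0,
             mean_centroid_dist_mm = 0, sd_centroid_dist_mm = 0,
             max_surface_dist_mm = 0, mtv_dispersion_cm3 = 0,
             burden_spread_mm = 0))
  }

  dmat <- sqrt(pmax(dist2_all(cent), 0))
  pair_d <- dmat[upper.tri(dmat)]
  bulk <- which.max(tlgs)

  # surface-to-surface: only pairs of voxels from different lesions
  surf_xyz <- list(); surf_lab <- integer(0)
  for (j in seq_len(nl)) {
    s <- surface_voxels(lesions$labels == j)
    xyz <- voxel_coords(s, spacing, lesions$origin)
    surf_xyz[[j]] <- xyz
    surf_lab <- c(surf_lab, rep(j, nrow(xyz)))
  }
  allxyz <- do.call(rbind, surf_xyz)
  d2 <- dist2_all(allxyz)
  same <- outer(surf_lab, surf_lab, "==")
  max_surf <- sqrt(max(d2[!same]))

  w <- mtvs / sum(mtvs)
  burden_centroid <- colSums(cent * w)
  spread <- mean(sqrt(rowSums(sweep(cent, 2, burden_centroid)^2)))

  c(n_lesions = nl,
    dmax_patient_mm = max(pair_d),
    dmax_bulk_mm = max(dmat[bulk, -bulk]),
    mean_centroid_dist_mm = mean(pair_d),
    sd_centroid_dist_mm = if (length(pair_d) > 1) sd(pair_d) else 0,
    max_surface_dist_mm = max_surf,
    mtv_dispersion_cm3 = sd(mtvs),
    burden_spread_mm = spread)
}
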