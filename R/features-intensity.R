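# First-order intensity features over the SUVs inside a lesion mask.
# Definitions follow the common first-order radiomics conventions:
# population moments for skewness/kurtosis (kurtosis not excess-corrected),
# energy as the sum of squared SUVs, entropy/uniformity on a fixed-width
# histogram of 64 bins spanning [0, max SUV of the region].

as_mask_array <- function(mask) {
  if (inherits(mask, "segmentation_mask")) mask <- mask$mask
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop_petsac("'mask' must be a 3D array", "petsac_format_error")
  mask != 0
}

masked_values <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"))
  mask <- as_mask_array(mask)
  if (!identical(dim(mask), dim(volume$values)))
    stop_petsac("mask and volume shapes differ", "petsac_alignment_error")
  v <- volume$values[mask]
  if (length(v) == 0)
    stop_petsac("empty mask: no voxels to quantify", "petsac_empty_error")
  v
}

#' First-order SUV statistics of a lesion
#'
#' @param volume a [pet_volume].
#' @param mask binary 3D array (or `segmentation_mask`) aligned to `volume`;
#'   must be non-empty.
#' @param n_bins histogram bins for entropy/uniformity (fixed width over
#'   `[0, max SUV]` of the region).
#' @return Named numeric vector: `suv_max`, `suv_min`, `suv_mean`,
#'   `suv_median`, `suv_sd`, `suv_range`, `suv_rms`, `suv_mad`, `skewness`,
#'   `kurtosis`, `energy`, `entropy`, `uniformity`.  `skewness`/`kurtosis`
#'   are `NA` for a zero-variance region.
#' @export
intensity_features <- function(volume, mask, n_bins = 64) {
  v <- masked_values(volume, mask)
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  p <- tabulate(pmin(pmax(ceiling(v / max(max(v), .Machine$double.eps) *
                                    n_bins), 1), n_bins), n_bins) / n
  p <- p[p > 0]
  c(suv_max = max(v),
    suv_min = min(v),
    suv_mean = m,
    suv_median = median(v),
    suv_sd = if (n > 1) sd(v) else 0,
    suv_range = max(v) - min(v),
    suv_rms = sqrt(mean(v^2)),
    suv_mad = mean(abs(v - m)),
    skewness = if (m2 > 0) mean((v - m)^3) / m2^1.5 else NA_real_,
    kurtosis = if (m2 > 0) mean((v - m)^4) / m2^2 else NA_real_,
    energy = sum(v^2),
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2))
}

#' SUVpeak: highest 3x3x3-neighborhood mean
#'
#' For every voxel of the mask, the mean SUV over the 3x3x3 voxel
#' neighborhood centered on it is computed; `suv_peak` is the maximum of
#' these means.  Neighborhoods may extend outside the mask (they sample the
#' surrounding volume) but are truncated at the volume borders: the mean is
#' taken over the neighbors that exist, rather than zero-padding, which
#' would bias edge peaks downward.
#'
#' @inheritParams intensity_features
#' @return A single SUV value; always `<= suv_max` of the same region.
#' @export
suv_peak <- function(volume, mask) {
  mask <- as_mask_array(mask)
  v <- volume$values
  if (!identical(dim(mask), dim(v)))
    stop_petsac("mask and volume shapes differ", "petsac_alignment_error")
  if (!any(mask))
    stop_petsac("empty mask: no voxels to quantify", "petsac_empty_error")
  nb_sum <- array(0, dim(v))
  nb_cnt <- array(0, dim(v))
  ones <- array(1, dim(v))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    nb_sum <- nb_sum + shift3d(v, dx, dy, dz, fill = 0)
    nb_cnt <- nb_cnt + shift3d(ones, dx, dy, dz, fill = 0)
  }
  max((nb_sum / nb_cnt)[mask])
}
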