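# Assembly of the per-lesion / per-patient feature table.  The default
# registry has 31 features: 14 intensity (incl. SUVpeak), MTV, TLG,
# 7 geometric and 8 dissemination.

#' Names of the default feature registry
#'
#' @return Character vector of the 31 default feature names, in table
#'   column order.
#' @export
feature_registry <- function() {
  c("suv_max", "suv_min", "suv_mean", "suv_median", "suv_sd", "suv_range",
    "suv_rms", "suv_mad", "skewness", "kurtosis", "energy", "entropy",
    "uniformity", "suv_peak", "mtv_cm3", "tlg_cm3",
    "surface_area_mm2", "surface_to_volume", "sphericity", "compactness1",
    "compactness2", "spherical_disproportion", "max_diameter_mm",
    "n_lesions", "dmax_patient_mm", "dmax_bulk_mm", "mean_centroid_dist_mm",
    "sd_centroid_dist_mm", "max_surface_dist_mm", "mtv_dispersion_cm3",
    "burden_spread_mm")
}

# intensity + geometry features of one binary mask (no dissemination scope)
single_region_features <- function(volume, mask, spacing) {
  c(intensity_features(volume, mask),
    suv_peak = suv_peak(volume, mask),
    mtv_cm3 = mtv(mask, spacing),
    tlg_cm3 = tlg(volume, mask, spacing),
    geometric_features(mask, spacing))
}

#' Feature table for one patient and one segmentation
#'
#' Computes the feature registry for every disconnected lesion
#' (`scope = "lesion_<j>"`) and for the union of all lesions
#' (`scope = "total_burden"`).  Dissemination features describe the whole
#' lesion set, so they are reported on the `total_burden` row only (and
#' `NA` on lesion rows, except `n_lesions = 1`).
#'
#' @param volume a [pet_volume].
#' @param lesions a `lesion_set` (from [label_lesions()]), or a
#'   `segmentation_mask` / logical array which is then component-labeled
#'   with `connectivity`.
#' @param patient_id,method_id,observer_id provenance strings copied into
#'   the rows.
#' @param connectivity used when `lesions` needs labeling.
#' @return A data frame with columns `patient_id`, `scope`, `lesion`,
#'   `method_id`, `observer_id`, then the feature registry columns.
#' @export
patient_features <- function(volume, lesions, patient_id = "patient",
                             method_id = NA_character_,
                             observer_id = NA_character_,
                             connectivity = 26) {
  if (!inherits(lesions, "lesion_set"))
    lesions <- label_lesions(lesions, connectivity)
  assert_aligned(volume, lesions, "volume and lesions")
  nl <- n_lesions(lesions)
  if (nl == 0)
    stop_petsac("no lesions to quantify", "petsac_empty_error")
  spacing <- lesions$spacing
  diss <- dissemination_features(lesions, volume)
  diss_names <- names(diss)

  rows <- vector("list", nl + 1)
  for (j in seq_len(nl)) {
    f <- single_region_features(volume, lesions$labels == j, spacing)
    d <- setNames(rep(NA_real_, length(diss_names)), diss_names)
    d["n_lesions"] <- 1
    rows[[j]] <- data.frame(patient_id = patient_id,
                            scope = fmt("lesion_%d", j), lesion = j,
                            method_id = method_id, observer_id = observer_id,
                            t(c(f, d)), check.names = FALSE)
  }
  union_mask <- lesions$labels > 0
  f <- single_region_features(volume, union_mask, spacing)
  rows[[nl + 1]] <- data.frame(patient_id = patient_id,
                               scope = "total_burden", lesion = NA_integer_,
                               method_id = method_id,
                               observer_id = observer_id,
                               t(c(f, diss)), check.names = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the representative lesion
#'
#' Picks, among the `lesion_*` rows of a feature table, the lesion
#' maximizing the criterion feature (`tlg_cm3` for `"highest_TLG"`,
#' `suv_max` for `"highest_SUVmax"`).  Ties are broken by larger MTV, then
#' by the smallest lesion id.
#'
#' @param features a data frame from [patient_features()] (one patient).
#' @param criterion `"highest_TLG"` or `"highest_SUVmax"`.
#' @return The selected lesion id (integer).
#' @export
select_representative <- function(features,
                                  criterion = c("highest_TLG",
                                                "highest_SUVmax")) {
  criterion <- match.arg(criterion)
  rows <- features[grepl("^lesion_", features$scope), , drop = FALSE]
  if (nrow(rows) == 0)
    stop_petsac("feature table has no lesion rows", "petsac_empty_error")
  key <- switch(criterion, highest_TLG = rows$tlg_cm3,
                highest_SUVmax = rows$suv_max)
  ord <- order(-key, -rows$mtv_cm3, rows$lesion)
  as.integer(rows$lesion[ord[1]])
}
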