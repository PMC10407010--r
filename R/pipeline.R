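# File-level pipeline commands wiring the modules into the workflow
# phantom -> per-ROI segmentation -> lesion features -> agreement.  These
# are the bodies of the command-line tool in `exec/petsac`; they read and
# write NIfTI/CSV/JSON only, so every run is reproducible from its files
# and recorded config.

write_sidecar <- function(path, payload) {
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Generate a phantom cohort on disk
#'
#' Writes, per patient, the PET volume, ground-truth label map and the
#' reference plus two observer ROI label maps as NIfTI files, and a cohort
#' manifest JSON recording the generation parameters and the seed.
#'
#' @param out_dir output directory (created if missing).
#' @param n_patients cohort size.
#' @param seed master seed.
#' @param ... passed to [phantom_cohort()].
#' @return The manifest, invisibly.
#' @export
run_phantom <- function(out_dir, n_patients = 1, seed = 1, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- phantom_cohort(n_patients, seed = seed, ...)
  entries <- lapply(cohort, function(pat) {
    base <- file.path(out_dir, pat$id)
    save_volume(pat$volume, paste0(base, "_pet.nii.gz"))
    save_rois(roi_set(pat$truth$labels, pat$truth$spacing),
              paste0(base, "_truth.nii.gz"))
    save_rois(pat$rois, paste0(base, "_rois.nii.gz"))
    save_rois(pat$obs1, paste0(base, "_rois_obs1.nii.gz"))
    save_rois(pat$obs2, paste0(base, "_rois_obs2.nii.gz"))
    list(id = pat$id, n_lesions = n_lesions(pat$truth),
         files = paste0(pat$id, c("_pet.nii.gz", "_truth.nii.gz",
                                  "_rois.nii.gz", "_rois_obs1.nii.gz",
                                  "_rois_obs2.nii.gz")))
  })
  manifest <- list(command = "phantom", n_patients = n_patients, seed = seed,
                   params = list(...), patients = entries)
  write_sidecar(file.path(out_dir, "cohort_manifest.json"), manifest)
  invisible(manifest)
}

#' Segment a PET volume inside ROIs and write the mask
#'
#' Runs one or more methods and writes, per method, a uint8 NIfTI mask
#' `<method>_mask.nii.gz` and a JSON sidecar recording the method, its
#' parameters, the per-ROI decisions (SAC coefficient and branch, applied
#' thresholds) and any warnings raised.
#'
#' @param pet_path path to the PET NIfTI (SUV units).
#' @param rois_path path to the ROI label-map NIfTI.
#' @param methods method identifiers (see [segmentation_methods()]).
#' @param out_dir output directory.
#' @param ... method parameters forwarded to [segment()].
#' @return Named list of `segmentation_mask` objects, invisibly.
#' @export
run_segment <- function(pet_path, rois_path, methods = "sac-bayes",
                        out_dir = ".", ...) {
  volume <- load_volume(pet_path)
  rois <- load_rois(rois_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (method in methods) {
    warnings_seen <- character(0)
    seg <- withCallingHandlers(
      segment(volume, rois, method = method, ...),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    mask_path <- file.path(out_dir, fmt("%s_mask.nii.gz", method))
    save_mask(seg, mask_path)
    write_sidecar(file.path(out_dir, fmt("%s_mask.json", method)),
                  list(command = "segment", method = method,
                       pet = pet_path, rois = rois_path,
                       params = seg$params, per_roi = seg$roi_info,
                       warnings = warnings_seen))
    out[[method]] <- seg
  }
  invisible(out)
}

#' Extract the feature table for one segmented patient
#'
#' Labels the mask into disconnected lesions and writes the per-lesion and
#' total-burden feature rows as tidy CSV, plus a JSON sidecar naming the
#' feature units.
#'
#' @param pet_path path to the PET NIfTI.
#' @param mask_path path to a binary mask NIfTI.
#' @param out_csv output CSV path.
#' @param patient_id,method_id,observer_id provenance strings.
#' @param connectivity lesion-splitting connectivity (6, 18, 26).
#' @return The feature data frame, invisibly.
#' @export
run_features <- function(pet_path, mask_path, out_csv,
                         patient_id = "patient", method_id = NA,
                         observer_id = NA, connectivity = 26) {
  volume <- load_volume(pet_path)
  mk <- load_mask(mask_path)
  lesions <- label_lesions(mk$mask, connectivity, spacing = mk$spacing,
                           origin = mk$origin)
  feats <- patient_features(volume, lesions, patient_id = patient_id,
                            method_id = method_id, observer_id = observer_id)
  dir.create(dirname(out_csv), recursive = TRUE, showWarnings = FALSE)
  write.csv(feats, out_csv, row.names = FALSE)
  units <- list(suv = "dimensionless (body-weight SUV)",
                mtv_cm3 = "cm^3", tlg_cm3 = "cm^3 (SUV-weighted)",
                surface_area_mm2 = "mm^2", surface_to_volume = "1/mm",
                distances = "mm", connectivity = connectivity)
  write_sidecar(paste0(out_csv, ".json"),
                list(command = "features", pet = pet_path, mask = mask_path,
                     units = units, features = feature_registry()))
  invisible(feats)
}

#' Evaluate agreement between mask files
#'
#' Computes all pairwise total-burden Dice coefficients between the given
#' masks and writes a per-pair CSV plus a JSON report with
#' median/IQR/max/min summaries per pair of sources across patients.
#'
#' @param mask_table data frame with columns `patient`, `source`, `path`
#'   (one binary-mask NIfTI per row).
#' @param out_prefix path prefix for `<prefix>_dice.csv` and
#'   `<prefix>_report.json`.
#' @return The per-pair Dice data frame, invisibly.
#' @export
run_evaluate <- function(mask_table, out_prefix) {
  stopifnot(all(c("patient", "source", "path") %in% names(mask_table)))
  rows <- list()
  for (pat in unique(mask_table$patient)) {
    sub <- mask_table[mask_table$patient == pat, , drop = FALSE]
    masks <- lapply(sub$path, function(p) load_mask(p)$mask)
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) for (j in seq((i + 1), nrow(sub))) {
      rows[[length(rows) + 1]] <-
        data.frame(patient = pat, source_a = sub$source[i],
                   source_b = sub$source[j],
                   dice = suppressWarnings(dice(masks[[i]], masks[[j]])))
    }
  }
  if (length(rows) == 0)
    stop_petsac("need at least two sources per patient", "petsac_domain_error")
  dice_df <- do.call(rbind, rows)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  write.csv(dice_df, paste0(out_prefix, "_dice.csv"), row.names = FALSE)
  pairs <- unique(dice_df[, c("source_a", "source_b")])
  summaries <- lapply(seq_len(nrow(pairs)), function(r) {
    sel <- dice_df$source_a == pairs$source_a[r] &
      dice_df$source_b == pairs$source_b[r]
    c(list(source_a = pairs$source_a[r], source_b = pairs$source_b[r]),
      as.list(summary_stats(dice_df$dice[sel])))
  })
  write_sidecar(paste0(out_prefix, "_report.json"),
                list(command = "evaluate", pairs = summaries))
  invisible(dice_df)
}
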