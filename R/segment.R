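# Per-ROI lesion segmentation.  Every method operates strictly inside each
# observer-drawn ROI: a voxel outside every ROI is never labeled lesion, and
# each ROI is segmented independently of the others.

new_segmentation_mask <- function(mask, per_roi, method_id, params,
                                  spacing, origin, roi_info) {
  structure(list(mask = mask, per_roi = per_roi, method_id = method_id,
                 params = params, spacing = spacing, origin = origin,
                 roi_info = roi_info),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(fmt("<segmentation_mask> method '%s', %d ROI(s), %d lesion voxel(s)\n",
          x$method_id, nrow(x$roi_info), sum(x$mask)))
  invisible(x)
}

# shared per-ROI driver: `select` maps (values, label) -> logical over the
# ROI's voxels, plus a one-row data.frame of method details
segment_by_roi <- function(volume, rois, method_id, params, select) {
  stopifnot(inherits(volume, "pet_volume"))
  stopifnot(inherits(rois, "roi_set"))
  assert_aligned(volume, rois, "PET volume and ROI set")
  shape <- dim(volume$values)
  mask <- array(FALSE, shape)
  per_roi <- list()
  info <- list()
  for (lab in seq_len(n_rois(rois))) {
    idx <- which(rois$labels == lab)
    vals <- volume$values[idx]
    res <- select(vals, lab)
    sel <- idx[res$keep]
    if (length(sel) == 0)
      warning(fmt("ROI %d: segmentation is empty", lab), call. = FALSE)
    mask[sel] <- TRUE
    per_roi[[as.character(lab)]] <- sel
    info[[lab]] <- cbind(data.frame(label = lab, n_roi = length(idx),
                                    n_selected = length(sel)), res$detail)
  }
  roi_info <- do.call(rbind, info)
  if (is.null(roi_info))
    roi_info <- data.frame(label = integer(), n_roi = integer(),
                           n_selected = integer())
  new_segmentation_mask(mask, per_roi, method_id, params,
                        volume$spacing, volume$origin, roi_info)
}

#' Absolute SUV threshold segmentation
#'
#' Within each ROI, keeps the voxels with `SUV >= threshold`.  The default
#' threshold of SUV 2.5 is the value commonly used to measure baseline
#' metabolic tumor volume in lymphoma.  Comparisons are boundary-inclusive.
#' An ROI whose voxels all fall below the threshold yields an empty per-ROI
#' mask and a warning.
#'
#' @param volume a [pet_volume] in SUV units.
#' @param rois an [roi_set] aligned to `volume`.
#' @param threshold absolute SUV cut-off (> 0).
#' @return A `segmentation_mask`: binary `mask`, per-ROI voxel index sets
#'   `per_roi`, and a `roi_info` data frame recording the threshold applied
#'   to each ROI.
#' @export
segment_threshold_abs <- function(volume, rois, threshold = 2.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  segment_by_roi(volume, rois, "abs25",
                 list(threshold = threshold),
                 function(vals, lab)
                   list(keep = vals >= threshold,
                        detail = data.frame(threshold = threshold)))
}

#' Relative (percentage-of-maximum) threshold segmentation
#'
#' Within each ROI, keeps the voxels with `SUV >= fraction * max(SUV)` where
#' the maximum is taken over that ROI alone, so the cut-off adapts per
#' lesion.  The default fraction 0.41 (41% of SUVmax) is the cut-off
#' recommended for solid-tumor volume delineation.
#'
#' @inheritParams segment_threshold_abs
#' @param fraction fraction of the per-ROI SUVmax, in (0, 1).
#' @return A `segmentation_mask` (see [segment_threshold_abs()]); `roi_info`
#'   records each ROI's cut-off.
#' @export
segment_threshold_rel <- function(volume, rois, fraction = 0.41) {
  stopifnot(is.numeric(fraction), length(fraction) == 1,
            fraction > 0, fraction < 1)
  segment_by_roi(volume, rois, "rel41",
                 list(fraction = fraction),
                 function(vals, lab) {
                   thr <- fraction * max(vals)
                   list(keep = vals >= thr,
                        detail = data.frame(threshold = thr))
                 })
}

fit_base <- function(base, vals, k, context) {
  switch(base,
         kmeans = kmeans_1d(vals, k, context = context),
         bayesian = fit_gmm_map(vals, k, context = context),
         stop_petsac(fmt("unknown base fitter '%s'", base),
                     "petsac_domain_error"))
}

#' Two-class clustering segmentation
#'
#' Fits `k` intensity classes inside each ROI with either percentile-
#' initialized k-means or the Gaussian-mixture MAP classifier, and takes the
#' highest-mean class as the lesion.
#'
#' @inheritParams segment_threshold_abs
#' @param base `"kmeans"` or `"bayesian"` (Gaussian-mixture MAP).
#' @param k number of classes (lesion = highest-mean class).
#' @return A `segmentation_mask`.
#' @export
segment_clustering <- function(volume, rois, base = c("kmeans", "bayesian"),
                               k = 2) {
  base <- match.arg(base)
  segment_by_roi(volume, rois, if (base == "kmeans") "kmeans" else "bayes",
                 list(base = base, k = k),
                 function(vals, lab) {
                   m <- fit_base(base, vals, k, fmt("ROI %d", lab))
                   list(keep = m$assignment == m$k,
                        detail = data.frame(k_fitted = m$k))
                 })
}

#' Self-adaptive configuration (SAC) segmentation
#'
#' For each ROI independently: fit 3 intensity classes with the base method,
#' compute the contrast coefficient `(m3 - m1) / (m3 + m1)`, and apply the
#' merge rule (see [sac_decide()]):
#' * `merge_two_lower` (`coef < 0.90`): the border class joins the
#'   background; the lesion is class 3 alone.
#' * `merge_two_higher` (`coef >= 0.94`): the border class joins the lesion;
#'   the lesion is classes 2 and 3.
#' * `two_classes`: refit with `k = 2`; the lesion is class 2.
#'
#' A degenerate ROI (too few distinct values for the fit, e.g. a noise-free
#' two-valued phantom ROI) falls back to the 41% relative threshold for that
#' ROI, with a warning; `roi_info$branch` records `"fallback_rel"` so batch
#' runs stay alive and auditable.
#'
#' @inheritParams segment_clustering
#' @param thresholds SAC cut-offs `(low, high)`; defaults `(0.90, 0.94)`.
#' @param fallback_fraction relative-threshold fraction used for degenerate
#'   ROIs.
#' @return A `segmentation_mask`; `roi_info` records each ROI's `coef` and
#'   `branch`.
#' @export
segment_sac <- function(volume, rois, base = c("bayesian", "kmeans"),
                        thresholds = c(0.90, 0.94),
                        fallback_fraction = 0.41) {
  base <- match.arg(base)
  method_id <- if (base == "kmeans") "sac-kmeans" else "sac-bayes"
  segment_by_roi(volume, rois, method_id,
                 list(base = base, thresholds = thresholds,
                      fallback_fraction = fallback_fraction),
                 function(vals, lab) {
    ctx <- fmt("ROI %d", lab)
    res <- tryCatch({
      m3 <- fit_base(base, vals, 3, ctx)
      if (m3$k != 3) stop_petsac(fmt("%s: 3-class fit collapsed", ctx),
                                 "petsac_degenerate_error")
      coef <- sac_coefficient(m3)
      decision <- sac_decide(coef, thresholds)
      keep <- switch(decision$branch,
        merge_two_lower = m3$assignment == 3,
        merge_two_higher = m3$assignment >= 2,
        two_classes = {
          m2 <- fit_base(base, vals, 2, ctx)
          m2$assignment == m2$k
        })
      list(keep = keep,
           detail = data.frame(coef = coef, branch = decision$branch))
    }, petsac_degenerate_error = function(e) {
      warning(fmt("%s: degenerate for %s SAC (%s); falling back to %.0f%% relative threshold",
                  ctx, base, conditionMessage(e), 100 * fallback_fraction),
              call. = FALSE)
      list(keep = vals >= fallback_fraction * max(vals),
           detail = data.frame(coef = NA_real_, branch = "fallback_rel"))
    })
    res
  })
}

#' Segment with a method selected by identifier
#'
#' Dispatcher over the six classical semiautomatic methods:
#' `"abs25"` (absolute SUV threshold), `"rel41"` (41% of per-ROI SUVmax),
#' `"kmeans"` / `"bayes"` (2-class clustering), and `"sac-kmeans"` /
#' `"sac-bayes"` (self-adaptive 3-class merge).
#'
#' @inheritParams segment_threshold_abs
#' @param method one of `"abs25"`, `"rel41"`, `"kmeans"`, `"bayes"`,
#'   `"sac-kmeans"`, `"sac-bayes"`.
#' @param ... passed to the underlying method function.
#' @return A `segmentation_mask`.
#' @export
segment <- function(volume, rois,
                    method = c("abs25", "rel41", "kmeans", "bayes",
                               "sac-kmeans", "sac-bayes"), ...) {
  method <- match.arg(method)
  switch(method,
         "abs25" = segment_threshold_abs(volume, rois, ...),
         "rel41" = segment_threshold_rel(volume, rois, ...),
         "kmeans" = segment_clustering(volume, rois, base = "kmeans", ...),
         "bayes" = segment_clustering(volume, rois, base = "bayesian", ...),
         "sac-kmeans" = segment_sac(volume, rois, base = "kmeans", ...),
         "sac-bayes" = segment_sac(volume, rois, base = "bayesian", ...))
}

#' All classical semiautomatic method identifiers
#' @return Character vector of the six method ids.
#' @export
segmentation_methods <- function() {
  c("abs25", "rel41", "kmeans", "bayes", "sac-kmeans", "sac-bayes")
}
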