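#' Region-of-interest label map
#'
#' An `roi_set` holds one integer label map aligned to a PET grid: 0 is
#' background and labels `1..K` (contiguous, no gaps) are observer-drawn
#' lesion-enclosing regions.  One label map holds all of a patient's ROIs;
#' ROIs therefore cannot overlap.
#'
#' @param labels 3D array of non-negative integers; positive labels must be
#'   the contiguous set `1..K`, each with at least one voxel.
#' @param spacing,origin grid geometry in mm (see [pet_volume]).
#' @return An object of class `roi_set` with fields `labels`, `spacing`,
#'   `origin`.
#' @export
roi_set <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3)
    stop_petsac("'labels' must be a 3D array", "petsac_format_error")
  lv <- as.vector(labels)
  if (any(!is.finite(lv)) || any(lv < 0) || any(lv != round(lv)))
    stop_petsac("ROI labels must be non-negative integers",
                "petsac_format_error")
  storage.mode(labels) <- "integer"
  pos <- sort(unique(lv[lv > 0]))
  if (length(pos) > 0 && !identical(as.integer(pos), seq_len(max(pos))))
    stop_petsac("positive ROI labels must be the contiguous set 1..K",
                "petsac_format_error")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop_petsac("'spacing' must be 3 strictly positive values (mm)",
                "petsac_format_error")
  structure(list(labels = labels, spacing = spacing, origin = origin),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(fmt("<roi_set> %s voxels, %d ROI(s)\n",
          paste(dim(x$labels), collapse = "x"), n_rois(x)))
  invisible(x)
}

#' Number of ROIs in a label map
#' @param rois an [roi_set].
#' @return Integer count `K`.
#' @export
n_rois <- function(rois) {
  stopifnot(inherits(rois, "roi_set"))
  as.integer(max(0L, max(rois$labels)))
}
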