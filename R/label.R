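#' Split a segmentation into disconnected lesions
#'
#' Connected-component labeling of a binary mask.  The default neighborhood
#' is 26-connectivity (faces, edges and corners), the most permissive
#' standard 3D convention, so two voxels touching only at a corner belong to
#' the same lesion; 6 and 18 are available for stricter conventions.
#' Components are labeled in descending voxel-count order (label 1 is the
#' largest lesion; ties broken by discovery order).
#'
#' @param mask a [segment()] result or a logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @param spacing,origin grid geometry, taken from `mask` when it is a
#'   `segmentation_mask`.
#' @return An object of class `lesion_set`: integer `labels` array
#'   (0 = background), `sizes` (voxels per lesion, descending),
#'   `connectivity`, `spacing`, `origin`.  An empty mask yields zero lesions.
#' @export
label_lesions <- function(mask, connectivity = 26,
                          spacing = NULL, origin = NULL) {
  if (inherits(mask, "segmentation_mask")) {
    spacing <- mask$spacing; origin <- mask$origin; mask <- mask$mask
  } else {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (is.null(origin)) origin <- c(0, 0, 0)
  }
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop_petsac("'mask' must be a 3D array", "petsac_format_error")
  if (!connectivity %in% c(6, 18, 26))
    stop_petsac("'connectivity' must be 6, 18 or 26", "petsac_domain_error")
  raw <- .label3d_cpp(as.logical(mask), as.integer(dim(mask)),
                      as.integer(connectivity))
  nlab <- max(raw)
  if (nlab == 0) {
    labels <- array(0L, dim(mask))
    sizes <- integer(0)
  } else {
    counts <- tabulate(raw[raw > 0], nlab)
    ord <- order(counts, decreasing = TRUE)          # stable: ties keep order
    remap <- integer(nlab); remap[ord] <- seq_len(nlab)
    labels <- array(0L, dim(mask))
    labels[raw > 0] <- remap[raw[raw > 0]]
    sizes <- counts[ord]
  }
  structure(list(labels = labels, sizes = sizes,
                 connectivity = as.integer(connectivity),
                 spacing = spacing, origin = origin),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(fmt("<lesion_set> %d lesion(s) under %d-connectivity; sizes: %s\n",
          n_lesions(x), x$connectivity,
          paste(utils::head(x$sizes, 8), collapse = ", ")))
  invisible(x)
}

#' Number of disconnected lesions
#' @param lesions a `lesion_set`.
#' @return Integer count.
#' @export
n_lesions <- function(lesions) {
  stopifnot(inherits(lesions, "lesion_set"))
  length(lesions$sizes)
}

#' Binary mask of one lesion
#' @param lesions a `lesion_set`.
#' @param j lesion label (1 = largest).
#' @return Logical 3D array.
#' @export
lesion_mask <- function(lesions, j) {
  stopifnot(inherits(lesions, "lesion_set"))
  if (!j %in% seq_along(lesions$sizes))
    stop_petsac(fmt("no lesion %s", j), "petsac_domain_error")
  lesions$labels == j
}
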