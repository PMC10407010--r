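#' PET volume in SUV units
#'
#' A `pet_volume` is a 3D scalar grid of body-weight standardized uptake
#' values (SUV, dimensionless) together with its physical geometry: per-axis
#' voxel size in mm and the physical position (mm) of the first voxel.
#' Voxel indexing is 0-based in physical terms, i.e. the center of voxel
#' `(i, j, k)` (1-based R indices) sits at `origin + (c(i, j, k) - 1) * spacing`.
#' The axis order is fixed to (x, y, z).
#'
#' @param values 3D numeric array of SUVs; all values must be finite and
#'   non-negative.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, physical position of the first voxel (mm).
#' @return An object of class `pet_volume` with fields `values`, `spacing`,
#'   `origin`.
#' @examples
#' vol <- pet_volume(array(1, dim = c(4, 4, 4)), spacing = c(4, 4, 4))
#' dim(vol$values)
#' @export
pet_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop_petsac("'values' must be a 3D array", "petsac_format_error")
  if (any(dim(values) < 1))
    stop_petsac("every axis must have length >= 1", "petsac_format_error")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop_petsac("SUV values must all be finite", "petsac_format_error")
  if (any(values < 0))
    stop_petsac("SUV values must be >= 0", "petsac_format_error")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_petsac("'spacing' must be 3 strictly positive values (mm)",
                "petsac_format_error")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop_petsac("'origin' must be 3 finite values (mm)", "petsac_format_error")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(fmt("<pet_volume> %s voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
          paste(dim(x$values), collapse = "x"),
          paste(format(x$spacing), collapse = "x"),
          min(x$values), max(x$values)))
  invisible(x)
}

#' SUV calibration factors
#'
#' Injected activity (MBq, decay-corrected to scan start) and body weight
#' (kg) needed to convert an activity-concentration volume to body-weight
#' SUV.
#'
#' @param injected_activity injected activity in MBq; > 0.
#' @param body_weight body weight in kg; > 0.
#' @return An object of class `suv_calibration`.
#' @export
suv_calibration <- function(injected_activity, body_weight) {
  if (!is.numeric(injected_activity) || length(injected_activity) != 1 ||
      !is.finite(injected_activity) || injected_activity <= 0)
    stop_petsac("'injected_activity' must be a single positive MBq value",
                "petsac_calibration_error")
  if (!is.numeric(body_weight) || length(body_weight) != 1 ||
      !is.finite(body_weight) || body_weight <= 0)
    stop_petsac("'body_weight' must be a single positive kg value",
                "petsac_calibration_error")
  structure(list(injected_activity = injected_activity,
                 body_weight = body_weight),
            class = "suv_calibration")
}

#' Convert an activity-concentration volume to body-weight SUV
#'
#' `SUV = activity [Bq/mL] * body_weight [g] / injected_activity [Bq]`.
#' Grid metadata (spacing, origin) is carried through unchanged.  Images are
#' assumed already decay-corrected to scan start by the scanner.
#'
#' @param activity a [pet_volume] whose values are activity concentration in
#'   Bq/mL (all >= 0).
#' @param calib a [suv_calibration].
#' @return A [pet_volume] in SUV units.
#' @examples
#' act <- pet_volume(array(5000, dim = c(2, 2, 2)))
#' suv <- to_suv(act, suv_calibration(370, 74))
#' suv$values[1]  # 1.0
#' @export
to_suv <- function(activity, calib) {
  stopifnot(inherits(activity, "pet_volume"))
  if (!inherits(calib, "suv_calibration"))
    stop_petsac("'calib' must be an suv_calibration object",
                "petsac_calibration_error")
  scale <- (calib$body_weight * 1000) / (calib$injected_activity * 1e6)
  pet_volume(activity$values * scale, activity$spacing, activity$origin)
}

# grid descriptor of any petsac spatial object
grid_of <- function(x) {
  if (inherits(x, "pet_volume"))
    list(shape = dim(x$values), spacing = x$spacing, origin = x$origin)
  else if (inherits(x, "roi_set"))
    list(shape = dim(x$labels), spacing = x$spacing, origin = x$origin)
  else if (inherits(x, "segmentation_mask") || inherits(x, "lesion_set"))
    list(shape = dim(x[[1]]), spacing = x$spacing, origin = x$origin)
  else stop_petsac("no grid for this object", "petsac_format_error")
}

#' Check that two objects live on the same voxel grid
#'
#' Pure predicate: `TRUE` iff the shapes are identical and spacing and origin
#' agree within an absolute tolerance.  Symmetric in its arguments.
#'
#' @param a,b `pet_volume`, `roi_set`, `segmentation_mask` or `lesion_set`
#'   objects.
#' @param tol absolute tolerance in mm for spacing/origin comparison.
#' @return `TRUE` or `FALSE`.
#' @export
check_alignment <- function(a, b, tol = 1e-3) {
  ga <- grid_of(a); gb <- grid_of(b)
  identical(ga$shape, gb$shape) &&
    all(abs(ga$spacing - gb$spacing) <= tol) &&
    all(abs(ga$origin - gb$origin) <= tol)
}

assert_aligned <- function(a, b, what = "inputs", tol = 1e-3) {
  if (!check_alignment(a, b, tol))
    stop_petsac(fmt("%s are not on the same voxel grid", what),
                "petsac_alignment_error")
  invisible(TRUE)
}
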