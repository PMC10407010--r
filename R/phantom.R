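# Digital PET phantoms: whole-body-like SUV volumes with ellipsoidal
# FDG-avid lesions on a uniform background, degraded by a Gaussian
# point-spread function and additive Gaussian noise, with enclosing ROIs
# derived from the ground truth and, optionally, perturbed "observer"
# variants.  Everything is reproducible from a single integer seed.

#' Separable 3D Gaussian smoothing
#'
#' Convolution with an axis-separable Gaussian kernel of the given full
#' width at half maximum, truncated at 3 standard deviations, with
#' replicate padding at the borders.  Used to emulate the scanner
#' point-spread function.
#'
#' @param values 3D numeric array.
#' @param fwhm_mm full width at half maximum in mm (0 = no smoothing).
#' @param spacing voxel size in mm per axis.
#' @return Smoothed array of the same shape.
#' @export
gaussian_blur <- function(values, fwhm_mm, spacing = c(1, 1, 1)) {
  stopifnot(is.array(values), length(dim(values)) == 3, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(values)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / spacing[ax]
    r <- ceiling(3 * sigma_vox)
    if (r < 1) next
    kern <- dnorm(-r:r, sd = sigma_vox)
    kern <- kern / sum(kern)
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(values, perm)
    dn <- dim(x)
    m <- matrix(x, nrow = dn[1])
    padded <- rbind(m[rep(1, r), , drop = FALSE], m,
                    m[rep(nrow(m), r), , drop = FALSE])
    f <- stats::filter(padded, kern, sides = 2)
    f <- f[(r + 1):(r + dn[1]), , drop = FALSE]
    values <- aperm(array(as.numeric(f), dn), order(perm))
  }
  values
}

#' Specification of a digital PET phantom
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel size in mm per axis.
#' @param background_suv uniform background SUV (> 0).
#' @param lesions list of lesions, each a list with `center` (mm), `radii`
#'   (mm; length 1 for a sphere or 3 for an ellipsoid) and `suv`
#'   (> `background_suv`: FDG-avid premise).  Lesions may overlap
#'   (conglomerates); a later lesion overwrites an earlier one where they
#'   do.
#' @param psf_fwhm point-spread FWHM in mm (0 = none).
#' @param noise_sd additive zero-mean Gaussian noise SD in SUV (0 = none);
#'   applied after blurring, then clipped at 0.
#' @param roi_margin ROI construction margin: each ground-truth lesion is
#'   dilated this many voxels (6-neighborhood steps) to form its ROI.
#' @param seed integer seed for the noise (`NULL` = use the current RNG
#'   stream).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 48), spacing = c(4, 4, 4),
                         background_suv = 1.0, lesions = list(),
                         psf_fwhm = 7, noise_sd = 0.1, roi_margin = 3,
                         seed = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  stopifnot(background_suv > 0, psf_fwhm >= 0, noise_sd >= 0,
            roi_margin >= 0)
  extent <- (shape - 1) * spacing
  for (les in lesions) {
    stopifnot(length(les$center) == 3, length(les$radii) %in% c(1, 3),
              all(les$radii > 0), length(les$suv) == 1)
    if (les$suv <= background_suv)
      stop_petsac("every lesion SUV must exceed the background SUV",
                  "petsac_spec_error")
    r3 <- rep(les$radii, length.out = 3)
    if (any(les$center - r3 < 0) || any(les$center + r3 > extent))
      stop_petsac("lesion extends outside the grid", "petsac_spec_error")
  }
  structure(list(shape = shape, spacing = spacing,
                 background_suv = background_suv, lesions = lesions,
                 psf_fwhm = psf_fwhm, noise_sd = noise_sd,
                 roi_margin = as.integer(roi_margin), seed = seed),
            class = "phantom_spec")
}

# lesion_set from a painted ground-truth label array (labels relabeled by
# descending voxel count to match the lesion_set convention)
truth_lesion_set <- function(gt, spacing) {
  nlab <- max(gt)
  if (nlab == 0) {
    sizes <- integer(0)
  } else {
    counts <- tabulate(gt[gt > 0], nlab)
    ord <- order(counts, decreasing = TRUE)
    remap <- integer(nlab); remap[ord] <- seq_len(nlab)
    gt[gt > 0] <- remap[gt[gt > 0]]
    sizes <- counts[ord]
  }
  structure(list(labels = gt, sizes = sizes, connectivity = 26L,
                 spacing = spacing, origin = c(0, 0, 0)),
            class = "lesion_set")
}

#' Generate a digital phantom
#'
#' Paints each lesion ellipsoid at its SUV over the uniform background
#' (later lesions overwrite earlier ones), applies the Gaussian
#' point-spread blur, adds zero-mean Gaussian noise (clipped at 0), and
#' derives one enclosing ROI per ground-truth lesion by dilating it
#' `roi_margin` voxels.  Where two dilated ROIs would overlap, the
#' lower-numbered lesion keeps the contested voxels.  Reproducible from
#' `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @return A list with `volume` ([pet_volume]), `truth` (`lesion_set` of the
#'   noise-free ground truth), and `rois` ([roi_set]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape; sp <- spec$spacing
  ax <- lapply(1:3, function(i) (seq_len(d[i]) - 1) * sp[i])
  vol <- array(spec$background_suv, d)
  gt <- array(0L, d)
  for (k in seq_along(spec$lesions)) {
    les <- spec$lesions[[k]]
    r3 <- rep(les$radii, length.out = 3)
    u2 <- lapply(1:3, function(i) ((ax[[i]] - les$center[i]) / r3[i])^2)
    inside <- outer(outer(u2[[1]], u2[[2]], "+"), u2[[3]], "+") <= 1
    vol[inside] <- les$suv
    gt[inside] <- k
  }
  clean <- vol
  if (spec$psf_fwhm > 0) vol <- gaussian_blur(vol, spec$psf_fwhm, sp)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, rnorm(length(vol), 0, spec$noise_sd))
    vol <- vol + noise
  }
  vol[vol < 0] <- 0

  # relabel the truth by descending size first so that ROI k always
  # encloses truth lesion k
  truth <- truth_lesion_set(gt, sp)
  rois <- array(0L, d)
  for (k in seq_along(truth$sizes)) {
    roi_k <- dilate_mask(truth$labels == k, spec$roi_margin,
                         connectivity = 6)
    claim <- roi_k & rois == 0
    rois[claim] <- k
    if (!any(claim))
      warning(fmt("ROI %d is empty after overlap resolution", k),
              call. = FALSE)
  }

  list(volume = pet_volume(vol, sp),
       truth = truth,
       rois = roi_set(rois, sp),
       clean = pet_volume(clean, sp))
}

#' Simulate an independent observer's ROI drawing
#'
#' Each ROI is independently dilated or eroded by a seeded random number of
#' steps in `[-magnitude, magnitude]`, with the structuring element
#' (6- or 26-neighborhood) re-drawn at random for every step, emulating a
#' second observer enclosing the same lesion with a slightly different
#' margin.  An erosion that would empty an ROI is skipped, so every ROI
#' keeps at least one voxel; ROIs never extend outside the grid.  Where a
#' dilated ROI would collide with another, the lower-numbered ROI keeps the
#' contested voxels.
#'
#' @param rois an [roi_set].
#' @param magnitude maximum perturbation in voxels (>= 0; 0 returns the
#'   input unchanged).
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return A perturbed [roi_set] with the same number of ROIs.
#' @export
perturb_roi <- function(rois, magnitude = 1, seed = NULL) {
  stopifnot(inherits(rois, "roi_set"), magnitude >= 0)
  if (magnitude == 0) return(rois)
  K <- n_rois(rois)
  with_seed(seed, {
    out <- array(0L, dim(rois$labels))
    for (k in seq_len(K)) {
      m <- rois$labels == k
      steps <- sample(seq(-magnitude, magnitude), 1)
      conn_pool <- c(6, 26)
      for (s in seq_len(abs(steps))) {
        conn <- sample(conn_pool, 1)
        m2 <- if (steps > 0) dilate_mask(m, 1, conn) else erode_mask(m, 1, conn)
        if (!any(m2)) break  # never erode an ROI away completely
        m <- m2
      }
      claim <- m & out == 0
      out[claim] <- k
    }
    roi_set(out, rois$spacing, rois$origin)
  })
}

#' Generate a cohort of phantom patients
#'
#' Samples, per patient, a lesion count, per-lesion volumes (converted to
#' mildly anisotropic ellipsoid radii), SUVs and positions, builds the
#' phantom, and simulates two observers (`obs1`, `obs2`) by perturbing the
#' reference ROIs by up to `perturb_magnitude` voxels.  Lesion centers are
#' rejection-sampled so that distinct lesions' ROIs (including the
#' perturbation allowance) cannot touch.  The default ranges emulate a
#' staging lymphoma population scanned on a ~7 mm-FWHM time-of-flight
#' system reconstructed on a 4 mm grid: lesion SUVmax 4.5-10.3 and MTV
#' 1.3-9.7 cm^3 (inter-quartile spans of a reported clinical cohort), on a
#' unit-SUV background with 10% noise.
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer master seed; every stochastic stage derives from it.
#' @param shape,spacing,background_suv,psf_fwhm,noise_sd,roi_margin see
#'   [phantom_spec()].
#' @param n_lesions_range integer range of lesions per patient.
#' @param suv_range lesion SUV sampling range.
#' @param mtv_range_cm3 lesion volume sampling range, cm^3.
#' @param perturb_magnitude observer ROI perturbation in voxels.
#' @return A list of patients; each is a list with `id`, `spec`, `volume`,
#'   `truth`, `rois` (reference), `obs1`, `obs2`.
#' @export
phantom_cohort <- function(n_patients, seed = NULL,
                           shape = c(48, 48, 48), spacing = c(4, 4, 4),
                           background_suv = 1.0,
                           n_lesions_range = c(1, 4),
                           suv_range = c(4.5, 10.3),
                           mtv_range_cm3 = c(1.3, 9.7),
                           psf_fwhm = 7, noise_sd = 0.1, roi_margin = 3,
                           perturb_magnitude = 1) {
  stopifnot(n_patients >= 1)
  with_seed(seed, {
    lapply(seq_len(n_patients), function(p) {
      n_les <- sample(seq(n_lesions_range[1], n_lesions_range[2]), 1)
      extent <- (shape - 1) * spacing
      clearance <- (roi_margin + perturb_magnitude + 2) * max(spacing)
      lesions <- list()
      centers <- matrix(numeric(0), 0, 3)
      radii_max <- numeric(0)
      for (k in seq_len(n_les)) {
        vol_cm3 <- runif(1, mtv_range_cm3[1], mtv_range_cm3[2])
        r_eq <- (3 * vol_cm3 * 1000 / (4 * pi))^(1 / 3)
        aniso <- runif(3, 0.8, 1.25)
        aniso <- aniso / prod(aniso)^(1 / 3)   # volume-preserving
        radii <- r_eq * aniso
        placed <- FALSE
        for (try in seq_len(200)) {
          margin_mm <- max(radii) + clearance
          if (any(extent < 2 * margin_mm)) break
          cen <- runif(3, margin_mm, extent - margin_mm)
          ok <- TRUE
          if (nrow(centers) > 0) {
            dmin <- sqrt(rowSums(sweep(centers, 2, cen)^2))
            ok <- all(dmin > radii_max + max(radii) + 2 * clearance)
          }
          if (ok) {
            lesions[[k]] <- list(center = cen, radii = radii,
                                 suv = runif(1, suv_range[1], suv_range[2]))
            centers <- rbind(centers, cen)
            radii_max <- c(radii_max, max(radii))
            placed <- TRUE
            break
          }
        }
        if (!placed) break  # grid full; patient keeps the lesions placed
      }
      if (length(lesions) == 0)
        stop_petsac("could not place any lesion; enlarge the grid",
                    "petsac_spec_error")
      sub_seeds <- sample.int(2^31 - 2, 3)
      spec <- phantom_spec(shape = shape, spacing = spacing,
                           background_suv = background_suv,
                           lesions = lesions, psf_fwhm = psf_fwhm,
                           noise_sd = noise_sd, roi_margin = roi_margin,
                           seed = sub_seeds[1])
      ph <- generate_phantom(spec)
      list(id = fmt("P%03d", p), spec = spec,
           volume = ph$volume, truth = ph$truth, rois = ph$rois,
           obs1 = perturb_roi(ph$rois, perturb_magnitude, sub_seeds[2]),
           obs2 = perturb_roi(ph$rois, perturb_magnitude, sub_seeds[3]))
    })
  })
}
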