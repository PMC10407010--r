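# Agreement between segmentations (Dice) and between feature sets
# (absolute-agreement intraclass correlation, two-way random effects,
# single measures: ICC(2,1)).

#' Dice coefficient between two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`.  Two empty masks are defined to agree
#' perfectly (Dice 1, with a warning); one empty mask gives 0.
#'
#' @param a,b logical 3D arrays (or `segmentation_mask` objects) of
#'   identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' m <- array(FALSE, c(2, 2, 2)); m2 <- m
#' m[1:2] <- TRUE; m2[2:3] <- TRUE
#' dice(m, m2)  # 2*1 / (2+2) = 0.5
#' @export
dice <- function(a, b) {
  a <- as_mask_array(a); b <- as_mask_array(b)
  if (!identical(dim(a), dim(b)))
    stop_petsac("mask shapes differ", "petsac_alignment_error")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both masks empty: Dice defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Patient-basis Dice between two segmentations
#'
#' Dice of the total tumor burdens: the per-ROI masks of each segmentation
#' are pooled into one union mask per source and compared.
#'
#' @param seg_a,seg_b `segmentation_mask` objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_patient_basis <- function(seg_a, seg_b) {
  stopifnot(inherits(seg_a, "segmentation_mask"),
            inherits(seg_b, "segmentation_mask"))
  assert_aligned(seg_a, seg_b, "segmentations")
  dice(seg_a$mask, seg_b$mask)
}

#' Absolute-agreement intraclass correlation, ICC(2,1)
#'
#' Two-way random effects, single-rater, absolute agreement:
#' `ICC(2,1) = (MSR - MSE) / (MSR + (m-1) MSE + m (MSC - MSE) / n)`
#' where `MSR`, `MSC`, `MSE` are the target (row), rater (column) and
#' residual mean squares of the two-way ANOVA without replication on an
#' `n x m` matrix.  Unlike the consistency form, systematic rater offsets
#' count as disagreement.  The mean squares come from a [stats::aov()] fit.
#'
#' @param ratings numeric matrix, `n >= 3` targets (rows) by `m >= 2` raters
#'   (columns), no missing cells.
#' @return The ICC value (can be slightly negative in noise); `NA` with a
#'   warning when the total variance is zero (agreement undefined).
#' @export
icc_absolute <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); m <- ncol(ratings)
  if (n < 3 || m < 2)
    stop_petsac("need at least 3 targets and 2 raters", "petsac_domain_error")
  if (any(!is.finite(ratings)))
    stop_petsac("ratings must be complete and finite", "petsac_domain_error")
  if (all(abs(ratings - mean(ratings)) < .Machine$double.eps * 1e2)) {
    warning("zero total variance: ICC undefined", call. = FALSE)
    return(NA_real_)
  }
  d <- data.frame(score = as.vector(ratings),
                  target = factor(rep(seq_len(n), m)),
                  rater = factor(rep(seq_len(m), each = n)))
  tab <- summary(aov(score ~ target + rater, data = d))[[1]]
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (m - 1) * mse + m * (msc - mse) / n)
}

summary_stats <- function(x) {
  x <- x[is.finite(x)]
  c(median = median(x), iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    max = max(x), min = min(x))
}

#' Pairwise agreement between segmentation sources over a phantom cohort
#'
#' For every patient of a cohort (see [phantom_cohort()]) and every
#' requested method, segments the patient's PET with each observer's ROI
#' variant, then reports:
#' * per-patient Dice between every pair of sources (a source is a
#'   method x observer combination), on the total-tumor-burden basis, plus
#'   Dice against the phantom ground truth;
#' * for each feature of the registry and each pair of sources, the
#'   absolute-agreement ICC(2,1) across patients, computed on the total
#'   burden and on both representative-lesion scopes (highest TLG, highest
#'   SUVmax);
#' * median / inter-quartile range / maximum / minimum summaries of each
#'   Dice pairing.
#'
#' @param cohort list of phantom patients from [phantom_cohort()].
#' @param methods method identifiers (see [segmentation_methods()]).
#' @param observers names of the ROI variants inside each patient (default
#'   `"obs1"`, `"obs2"`).
#' @param icc_features features to report ICC for.
#' @param connectivity connectivity for lesion labeling.
#' @return An object of class `agreement_report`: `dice` (long data frame),
#'   `dice_summary`, `icc` (long data frame), and `sources`.
#' @export
agreement_suite <- function(cohort, methods = c("sac-bayes", "rel41"),
                            observers = c("obs1", "obs2"),
                            icc_features = c("suv_max", "suv_peak",
                                             "suv_mean", "mtv_cm3",
                                             "tlg_cm3"),
                            connectivity = 26) {
  stopifnot(length(cohort) >= 1, length(observers) >= 1)
  sources <- expand.grid(method = methods, observer = observers,
                         stringsAsFactors = FALSE)
  source_id <- function(i) fmt("%s|%s", sources$method[i], sources$observer[i])

  dice_rows <- list()
  feat_rows <- list()
  for (p in seq_along(cohort)) {
    pat <- cohort[[p]]
    segs <- list()
    for (i in seq_len(nrow(sources))) {
      segs[[source_id(i)]] <- suppressWarnings(
        segment(pat$volume, pat[[sources$observer[i]]],
                method = sources$method[i]))
    }
    gt <- pat$truth$labels > 0
    for (i in seq_len(nrow(sources))) {
      si <- source_id(i)
      dice_rows[[length(dice_rows) + 1]] <-
        data.frame(patient = pat$id, source_a = si, source_b = "ground_truth",
                   dice = suppressWarnings(dice(segs[[si]]$mask, gt)))
      if (i < nrow(sources)) for (j in seq((i + 1), nrow(sources))) {
        sj <- source_id(j)
        dice_rows[[length(dice_rows) + 1]] <-
          data.frame(patient = pat$id, source_a = si, source_b = sj,
                     dice = suppressWarnings(
                       dice_patient_basis(segs[[si]], segs[[sj]])))
      }
      if (any(segs[[si]]$mask)) {
        les <- label_lesions(segs[[si]], connectivity)
        ft <- patient_features(pat$volume, les, patient_id = pat$id,
                               method_id = sources$method[i],
                               observer_id = sources$observer[i])
        ft$source <- si
        feat_rows[[length(feat_rows) + 1]] <- ft
      }
    }
  }
  dice_df <- do.call(rbind, dice_rows)
  feats <- do.call(rbind, feat_rows)

  # per-scope feature value of one source for one patient
  scope_value <- function(ft, scope, feature) {
    if (scope == "total_burden")
      return(ft[ft$scope == "total_burden", feature])
    crit <- if (scope == "highest_TLG") "highest_TLG" else "highest_SUVmax"
    j <- select_representative(ft, crit)
    ft[ft$scope == fmt("lesion_%d", j), feature]
  }

  icc_rows <- list()
  ids <- vapply(seq_len(nrow(sources)), source_id, character(1))
  patients <- unique(dice_df$patient)
  if (length(patients) >= 3 && nrow(sources) >= 2) {
    for (scope in c("total_burden", "highest_TLG", "highest_SUVmax")) {
      for (feature in icc_features) {
        for (i in seq_len(nrow(sources) - 1)) for (j in seq((i + 1), nrow(sources))) {
          vals <- vapply(patients, function(pid) {
            v <- vapply(c(ids[i], ids[j]), function(s) {
              ft <- feats[feats$patient_id == pid & feats$source == s, ,
                          drop = FALSE]
              if (nrow(ft) == 0) return(NA_real_)
              scope_value(ft, scope, feature)
            }, numeric(1))
            v
          }, numeric(2))
          mat <- t(vals)
          mat <- mat[stats::complete.cases(mat), , drop = FALSE]
          icc <- if (nrow(mat) >= 3)
            suppressWarnings(icc_absolute(mat)) else NA_real_
          icc_rows[[length(icc_rows) + 1]] <-
            data.frame(scope = scope, feature = feature,
                       source_a = ids[i], source_b = ids[j],
                       n = nrow(mat), icc = icc)
        }
      }
    }
  }
  icc_df <- if (length(icc_rows)) do.call(rbind, icc_rows) else
    data.frame(scope = character(), feature = character(),
               source_a = character(), source_b = character(),
               n = integer(), icc = numeric())

  pairs <- unique(dice_df[, c("source_a", "source_b")])
  summ <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    sel <- dice_df$source_a == pairs$source_a[r] &
      dice_df$source_b == pairs$source_b[r]
    cbind(pairs[r, , drop = FALSE], t(summary_stats(dice_df$dice[sel])))
  }))
  rownames(summ) <- NULL

  structure(list(dice = dice_df, dice_summary = summ, icc = icc_df,
                 sources = ids, features = feats),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(fmt("<agreement_report> %d source(s), %d patient(s)\n",
          length(x$sources), length(unique(x$dice$patient))))
  print(x$dice_summary, digits = 3)
  invisible(x)
}
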