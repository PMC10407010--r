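# The self-adaptive configuration (SAC) rule: from a 3-class fit of the ROI
# intensities, a contrast coefficient decides whether the middle "border"
# class joins the background, joins the lesion, or whether a plain 2-class
# segmentation should be used instead.

#' SAC contrast coefficient
#'
#' `coef = (m3 - m1) / (m3 + m1)` where `m1` and `m3` are the lowest and
#' highest class mean SUVs of a 3-class fit.  Because SUVs are non-negative
#' the coefficient always lies in `[0, 1]`; it is the asymmetry index of the
#' background and lesion class means and measures lesion-to-background
#' contrast.
#'
#' @param model a `cluster_model` with `k = 3` (means ascending).
#' @return The coefficient, a single number in `[0, 1]`.
#' @examples
#' m <- kmeans_1d(c(rep(0.6, 5), rep(10, 5), rep(19.4, 5)), k = 3)
#' sac_coefficient(m)  # (19.4 - 0.6) / 20 = 0.94
#' @export
sac_coefficient <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$k != 3)
    stop_petsac("SAC coefficient is defined for a 3-class model",
                "petsac_degenerate_error")
  m1 <- model$means[1]; m3 <- model$means[3]
  if (m1 + m3 <= 0)
    stop_petsac("all-zero region: m1 + m3 = 0", "petsac_degenerate_error")
  (m3 - m1) / (m3 + m1)
}

#' SAC merge decision
#'
#' Empirical rule on the contrast coefficient:
#' * `coef < low` (default 0.90): merge the two lower classes — the border
#'   class joins the background and the lesion is the highest class alone;
#' * `coef >= high` (default 0.94): merge the two higher classes — the border
#'   class joins the lesion;
#' * otherwise: discard the 3-class fit and segment with just 2 classes.
#'
#' The default cut-offs are the rule's published operating points.
#'
#' @param coef contrast coefficient in `[0, 1]`.
#' @param thresholds numeric length-2 `(low, high)` with
#'   `0 <= low < high <= 1`.
#' @return An object of class `sac_decision` with fields `coef`, `branch`
#'   (one of `"merge_two_lower"`, `"merge_two_higher"`, `"two_classes"`) and
#'   `thresholds`.
#' @examples
#' sac_decide(0.80)$branch  # merge_two_lower
#' sac_decide(0.94)$branch  # merge_two_higher
#' sac_decide(0.92)$branch  # two_classes
#' @export
sac_decide <- function(coef, thresholds = c(0.90, 0.94)) {
  if (!is.numeric(coef) || length(coef) != 1 || !is.finite(coef) ||
      coef < 0 || coef > 1)
    stop_petsac("'coef' must be a single value in [0, 1]",
                "petsac_domain_error")
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 2 || thresholds[1] < 0 || thresholds[2] > 1 ||
      thresholds[1] >= thresholds[2])
    stop_petsac("'thresholds' must satisfy 0 <= low < high <= 1",
                "petsac_domain_error")
  branch <- if (coef < thresholds[1]) "merge_two_lower"
            else if (coef >= thresholds[2]) "merge_two_higher"
            else "two_classes"
  structure(list(coef = coef, branch = branch, thresholds = thresholds),
            class = "sac_decision")
}

#' @export
print.sac_decision <- function(x, ...) {
  cat(fmt("<sac_decision> coef = %.4f -> %s (cut-offs %.2f / %.2f)\n",
          x$coef, x$branch, x$thresholds[1], x$thresholds[2]))
  invisible(x)
}
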