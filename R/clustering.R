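# 1D intensity clustering: percentile-initialized Lloyd k-means and a
# univariate Gaussian-mixture EM with maximum-a-posteriori voxel assignment.
# These are the engines behind the "k-means" and "Bayesian" segmentation
# methods; both are fully deterministic (no random initialization).

new_cluster_model <- function(k, means, assignment, variances = NULL,
                              weights = NULL, method, iterations,
                              converged = TRUE) {
  structure(list(k = as.integer(k), means = means, variances = variances,
                 weights = weights, assignment = as.integer(assignment),
                 method = method, iterations = as.integer(iterations),
                 converged = isTRUE(converged)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(fmt("<cluster_model> %s, k = %d, means = %s\n", x$method, x$k,
          paste(signif(x$means, 4), collapse = ", ")))
  invisible(x)
}

# relabel classes so class 1 has the lowest mean; drops nothing
relabel_ascending <- function(means, assignment, ...) {
  o <- order(means)
  extras <- lapply(list(...), function(v) if (is.null(v)) NULL else v[o])
  c(list(means = means[o], assignment = match(assignment, o)), extras)
}

#' Percentile-initialized 1D k-means
#'
#' Lloyd's algorithm on a vector of SUVs.  Initial centroid `i` of `k` is the
#' `100 * (2i - 1) / (2k)` percentile of the value distribution
#' (linear-interpolation definition), which spreads the starting centroids
#' over the observed distribution and makes the fit deterministic.
#' Iteration stops when no assignment changes or after `max_iter` sweeps.
#' Classes are relabeled in ascending order of mean.  If, at convergence,
#' two classes have equal means or a class is empty, the duplicates are
#' merged and the fit is re-run with `k - 1` classes; if `k` would fall
#' below 2 the input is reported as degenerate.
#'
#' @param values numeric vector of SUVs (finite; `length(values) >= k`).
#' @param k number of classes (>= 2).
#' @param max_iter iteration cap for Lloyd sweeps.
#' @param context label used in error messages (e.g. which ROI is being fit).
#' @return A `cluster_model` with fields `k`, `means` (ascending),
#'   `assignment` (class index per value), `iterations`, `converged`.
#' @examples
#' m <- kmeans_1d(c(1, 1, 1, 9, 9, 9), k = 2)
#' m$means       # 1, 9
#' m$assignment  # 1 1 1 2 2 2
#' @export
kmeans_1d <- function(values, k, max_iter = 300, context = "input") {
  values <- as.numeric(values)
  if (any(!is.finite(values)))
    stop_petsac(fmt("%s: values must be finite", context),
                "petsac_degenerate_error")
  k <- as.integer(k)
  if (k < 2) stop_petsac(fmt("%s: k must be >= 2", context),
                         "petsac_degenerate_error")
  if (length(values) < k)
    stop_petsac(fmt("%s: need at least k = %d values", context, k),
                "petsac_degenerate_error")
  if (length(unique(values)) < k)
    stop_petsac(fmt("%s: fewer than k = %d distinct values", context, k),
                "petsac_degenerate_error")

  centers <- as.numeric(quantile(values, probs = (2 * seq_len(k) - 1) / (2 * k),
                                 type = 7, names = FALSE))
  assignment <- integer(length(values))
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    d <- abs(outer(values, centers, "-"))
    new_assignment <- max.col(-d, ties.method = "first")
    if (identical(new_assignment, assignment)) { converged <- TRUE; break }
    assignment <- new_assignment
    for (j in seq_len(k)) {
      members <- assignment == j
      if (any(members)) centers[j] <- mean(values[members])
    }
  }

  counts <- tabulate(assignment, k)
  sorted <- sort(centers)
  if (any(counts == 0) || any(diff(sorted) <= 0)) {
    # empty class or tied means: merge and refit with one class fewer
    if (k - 1 < 2)
      stop_petsac(fmt("%s: clustering degenerated to a single class", context),
                  "petsac_degenerate_error")
    return(kmeans_1d(values, k - 1, max_iter, context))
  }
  r <- relabel_ascending(centers, assignment)
  new_cluster_model(k, r$means, r$assignment, method = "kmeans",
                    iterations = it, converged = converged)
}

#' Gaussian-mixture MAP classification of 1D SUVs
#'
#' Fits a `k`-component univariate Gaussian mixture by
#' expectation-maximization and assigns each value to the class with maximum
#' posterior probability.  The fit is initialized from
#' [kmeans_1d()] (class means, proportions and within-class variances), so it
#' is deterministic.  EM stops when the mean log-likelihood gain per sample
#' drops below `tol` or after `max_iter` iterations; non-convergence returns
#' the last iterate with `converged = FALSE` and a warning.  Variances are
#' floored at `1e-8` times the overall variance (with a warning when the
#' floor binds) so point-mass classes cannot collapse the likelihood.
#'
#' @param values numeric vector of SUVs; `length(values) >= 5 * k`.
#' @param k number of mixture components (>= 2).
#' @param tol per-sample log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param context label used in error messages.
#' @return A `cluster_model` with `means` (ascending), `variances`,
#'   `weights`, MAP `assignment`, `iterations`, `converged`.
#' @export
fit_gmm_map <- function(values, k, tol = 1e-6, max_iter = 500,
                        context = "input") {
  values <- as.numeric(values)
  k <- as.integer(k)
  n <- length(values)
  if (n < 5 * k)
    stop_petsac(fmt("%s: need at least 5k = %d values for a %d-component mixture",
                    context, 5 * k, k), "petsac_degenerate_error")
  init <- kmeans_1d(values, k, context = context)

  overall_var <- mean((values - mean(values))^2)
  var_floor <- 1e-8 * overall_var
  mu <- init$means
  w <- tabulate(init$assignment, k) / n
  s2 <- vapply(seq_len(k), function(j) {
    x <- values[init$assignment == j]
    mean((x - mean(x))^2)
  }, numeric(1))
  floored <- s2 < var_floor
  s2 <- pmax(s2, var_floor)

  log_resp <- function(mu, s2, w) {
    ld <- vapply(seq_len(k), function(j)
      dnorm(values, mu[j], sqrt(s2[j]), log = TRUE) + log(w[j]), numeric(n))
    mx <- ld[cbind(seq_len(n), max.col(ld, ties.method = "first"))]
    lse <- mx + log(rowSums(exp(ld - mx)))
    list(ld = ld, lse = lse, ll = sum(lse))
  }

  ll_old <- -Inf
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    e <- log_resp(mu, s2, w)
    resp <- exp(e$ld - e$lse)
    nk <- colSums(resp)
    if (any(nk < .Machine$double.eps * n)) break  # a component died
    w <- nk / n
    mu <- colSums(resp * values) / nk
    s2_new <- colSums(resp * (outer(values, mu, "-"))^2) / nk
    floored <- floored | (s2_new < var_floor)
    s2 <- pmax(s2_new, var_floor)
    if (e$ll - ll_old < tol * n && it > 1) { converged <- TRUE; break }
    ll_old <- e$ll
  }
  if (any(floored))
    warning(fmt("%s: mixture variance floored at 1e-8 x overall variance",
                context), call. = FALSE)
  if (!converged)
    warning(fmt("%s: EM did not converge in %d iterations; best iterate used",
                context, max_iter), call. = FALSE)

  e <- log_resp(mu, s2, w)
  assignment <- max.col(e$ld, ties.method = "first")

  counts <- tabulate(assignment, k)
  sorted <- sort(mu)
  if (any(counts == 0) || any(diff(sorted) <= 0)) {
    if (k - 1 < 2)
      stop_petsac(fmt("%s: mixture degenerated to a single class", context),
                  "petsac_degenerate_error")
    return(fit_gmm_map(values, k - 1, tol, max_iter, context))
  }
  r <- relabel_ascending(mu, assignment, variances = s2, weights = w)
  new_cluster_model(k, r$means, r$assignment, variances = r$variances,
                    weights = r$weights, method = "bayesian",
                    iterations = it, converged = converged)
}
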