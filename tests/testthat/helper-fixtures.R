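# Fixtures and independent oracles shared across test files.  Everything is
# generated in code; oracles are deliberately naive (loops, enumeration).

# volume with a given value vector reshaped into shape
vol3 <- function(values, shape = c(4, 4, 4), spacing = c(1, 1, 1)) {
  pet_volume(array(values, dim = shape), spacing = spacing)
}

# single ROI covering the given linear indices
roi_over <- function(idx, shape = c(4, 4, 4), spacing = c(1, 1, 1)) {
  lab <- array(0L, shape)
  lab[idx] <- 1L
  roi_set(lab, spacing = spacing)
}

# naive flood-fill connected-component oracle (queue-based, R loops)
label_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- petsac:::neighbor_offsets(connectivity)
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      z <- (v - 1) %/% (d[1] * d[2])
      y <- ((v - 1) %% (d[1] * d[2])) %/% d[1]
      x <- (v - 1) %% d[1]
      for (q in seq_len(nrow(offs))) {
        xx <- x + offs[q, 1]; yy <- y + offs[q, 2]; zz <- z + offs[q, 3]
        if (xx < 0 || xx >= d[1] || yy < 0 || yy >= d[2] ||
            zz < 0 || zz >= d[3]) next
        w <- zz * d[1] * d[2] + yy * d[1] + xx + 1
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# exhaustive 3x3x3 neighborhood-mean scan (border-truncated)
suv_peak_oracle <- function(values, mask) {
  d <- dim(values)
  best <- -Inf
  for (s in which(mask)) {
    z <- (s - 1) %/% (d[1] * d[2]) + 1
    y <- ((s - 1) %% (d[1] * d[2])) %/% d[1] + 1
    x <- (s - 1) %% d[1] + 1
    acc <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx >= 1 && xx <= d[1] && yy >= 1 && yy <= d[2] &&
          zz >= 1 && zz <= d[3])
        acc <- c(acc, values[xx, yy, zz])
    }
    best <- max(best, mean(acc))
  }
  best
}

# ICC(2,1) by explicit two-way ANOVA sums of squares
icc21_oracle <- function(x) {
  n <- nrow(x); m <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- m * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (m - 1)
  mse <- ss_err / ((n - 1) * (m - 1))
  (msr - mse) / (msr + (m - 1) * mse + m * (msc - mse) / n)
}

# consistency ICC(3,1) oracle, used to contrast with absolute agreement
icc31_oracle <- function(x) {
  n <- nrow(x); m <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- m * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((x - grand)^2) - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (m - 1))
  (msr - mse) / (msr + (m - 1) * mse)
}

# one-sphere phantom helpers
sphere_phantom <- function(suv = 6, radius = 12, shape = c(24, 24, 24),
                           spacing = c(4, 4, 4), background = 1,
                           psf_fwhm = 0, noise_sd = 0, seed = 11,
                           roi_margin = 3) {
  center <- (shape - 1) * spacing / 2
  generate_phantom(phantom_spec(
    shape = shape, spacing = spacing, background_suv = background,
    lesions = list(list(center = center, radii = radius, suv = suv)),
    psf_fwhm = psf_fwhm, noise_sd = noise_sd, roi_margin = roi_margin,
    seed = seed))
}

# Lloyd k-means oracle via stats::kmeans with the same percentile init
kmeans_lloyd_oracle <- function(values, k) {
  init <- as.numeric(quantile(values, probs = (2 * seq_len(k) - 1) / (2 * k),
                              type = 7, names = FALSE))
  fit <- stats::kmeans(values, centers = matrix(init, ncol = 1),
                       algorithm = "Lloyd", iter.max = 300)
  o <- order(fit$centers)
  list(means = as.numeric(fit$centers)[o],
       assignment = match(fit$cluster, o))
}
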