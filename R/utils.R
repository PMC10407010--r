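# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
# `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# abort with a classed condition so callers can distinguish error families
stop_petsac <- function(msg, class) {
  stop(structure(
    class = c(class, "petsac_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

fmt <- function(...) sprintf(...)

# 3D array shifted by (dx, dy, dz) voxels, vacated voxels filled with `fill`
shift3d <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  src <- list(sx - dx, sy - dy, sz - dz)
  keep <- lapply(seq_len(3), function(i) src[[i]] >= 1 & src[[i]] <= d[i])
  out[sx[keep[[1]]], sy[keep[[2]]], sz[keep[[3]]]] <-
    a[src[[1]][keep[[1]]], src[[2]][keep[[2]]], src[[3]][keep[[3]]]]
  out
}

# offsets of the 6/18/26-neighborhoods (excluding the center)
neighbor_offsets <- function(connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  as.matrix(g[keep, , drop = FALSE])
}
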