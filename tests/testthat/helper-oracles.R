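# Independent brute-force oracles: literal double-loop transcriptions of the
# statistic definitions, kept free of any package internals.

oracle_moran <- function(x, W) {
  x <- unname(x)
  n <- length(x)
  xb <- mean(x)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
      s0 <- s0 + W[i, j]
    }
  }
  n * num / (s0 * sum((x - xb)^2))
}

oracle_g <- function(x, W) {
  x <- unname(x)
  n <- length(x)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      num <- num + W[i, j] * x[i] * x[j]
      den <- den + x[i] * x[j]
    }
  }
  num / den
}

oracle_local_moran <- function(x, W) {
  x <- unname(x)
  n <- length(x)
  xb <- mean(x)
  m2 <- sum((x - xb)^2) / n
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i) s <- s + W[i, j] * (x[j] - xb)
    (x[i] - xb) / m2 * s
  }, 0)
}

oracle_local_gi <- function(x, W, star = FALSE) {
  x <- unname(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      if (j == i) {
        if (star) { num <- num + x[j]; den <- den + x[j] }
      } else {
        num <- num + W[i, j] * x[j]
        den <- den + x[j]
      }
    }
    num / den
  }, 0)
}

# Square-lattice region set built directly from coordinates (no generator).
grid_rs <- function(side, spacing = 1) {
  g <- expand.grid(col = 0:(side - 1), row = 0:(side - 1))
  region_set(sprintf("g%d", seq_len(nrow(g))),
             cbind(g$row, g$col) * spacing)
}

# Random test instance: region set with uniform centroids (or a grid), a
# distance-band weight matrix guaranteed link-complete, and positive values.
random_instance <- function(n, grid = FALSE) {
  rs <- if (grid) {
    side <- ceiling(sqrt(n))
    grid_rs(side)
  } else {
    region_set(sprintf("r%d", seq_len(n)),
               cbind(runif(n, 0, 10), runif(n, 0, 10)))
  }
  w <- distance_band(rs)
  x <- rlnorm(rs$n, 0, 0.6)
  names(x) <- rs$ids
  list(rs = rs, w = w, x = x)
}
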