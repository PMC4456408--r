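# Independent brute-force oracles used to validate the graph solver.

# All closed subsets of a digraph by exhaustive enumeration (<= ~16 nodes).
brute_min_closed_set <- function(weights, edges) {
  n <- length(weights)
  best <- 0
  best_set <- integer(0)
  for (m in 0:(2^n - 1)) {
    S <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    closed <- nrow(edges) == 0L ||
      all(!(edges[, 1] %in% S) | (edges[, 2] %in% S))
    if (closed) {
      w <- sum(weights[S])
      if (w < best - 1e-12) { best <- w; best_set <- S }
    }
  }
  list(weight = best, set = best_set)
}

# random DAG on n nodes (edges only from lower to higher index)
random_dag <- function(n, p = 0.3) {
  e <- which(upper.tri(matrix(TRUE, n, n)) &
               matrix(stats::runif(n * n) < p, n, n), arr.ind = TRUE)
  matrix(as.integer(e), ncol = 2L)
}

# exhaustive search over every feasible surface of a small cost volume
# (product-space enumeration, vectorized over candidate surfaces)
brute_min_surface <- function(cost, dx, dy, z_lo, z_hi) {
  d <- dim(cost); nx <- d[1]; ny <- d[2]
  ncols <- nx * ny
  grid <- as.matrix(expand.grid(rep(list(z_lo:z_hi), ncols)))
  ok <- rep(TRUE, nrow(grid))
  colx <- (seq_len(ncols) - 1L) %% nx + 1L
  coly <- (seq_len(ncols) - 1L) %/% nx + 1L
  for (i in seq_len(ncols)) for (j in seq_len(ncols)) {
    if (colx[j] == colx[i] + 1L && coly[j] == coly[i])
      ok <- ok & abs(grid[, j] - grid[, i]) <= dx
    if (coly[j] == coly[i] + 1L && colx[j] == colx[i])
      ok <- ok & abs(grid[, j] - grid[, i]) <= dy
  }
  tot <- rep(0, nrow(grid))
  for (i in seq_len(ncols))
    tot <- tot + cost[colx[i] + (coly[i] - 1L) * nx + grid[, i] * ncols]
  tot[!ok] <- Inf
  best <- which.min(tot)
  list(cost = tot[best],
       z = matrix(grid[best, ], nx, ny))
}

# small fast phantom spec for unit tests
tiny_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(dims = c(16L, 8L, 64L),
         spacing = c(6 / 16, 6 / 8, 2 * 2.3 / 885),
         pit_radius_mm = 2.0, pit_depth_mm = 0.08),
    list(...))
  do.call(phantom_spec, args)
}
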