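# Shared fixtures: everything is generated in code at test time.

# small grid for pure-numerics tests
tiny_grid <- function(n = 8L, vox = 4) voxel_grid(rep(n, 3L), vox)

# coarse but head-compatible grid (FOV 128 mm) for anatomy-based tests
coarse_cfg <- function(...) {
  cohort_config(grid_shape = c(32L, 32L, 32L), voxel_size_mm = 4, ...)
}

random_field <- function(grid, seed, sd = 50) {
  fieldshim:::with_seed(seed, {
    v <- array(rnorm(prod(grid$shape), 0, sd), grid$shape)
    field_map(v, grid)
  })
}

# independent normal-equations oracle for masked harmonic least squares
oracle_lsq <- function(B, y, idx) {
  X <- B[idx, , drop = FALSE]
  solve(crossprod(X), crossprod(X, y[idx]))[, 1]
}

# 4th-order accurate finite-difference Laplacian (exact for polynomials
# up to degree 5); interior voxels only
fd_laplacian <- function(v, h) {
  d <- dim(v)
  i <- 3:(d[1] - 2); j <- 3:(d[2] - 2); k <- 3:(d[3] - 2)
  lap1 <- function(f2m, f1m, f0, f1p, f2p, hh)
    (-f2p + 16 * f1p - 30 * f0 + 16 * f1m - f2m) / (12 * hh^2)
  lap1(v[i - 2, j, k], v[i - 1, j, k], v[i, j, k], v[i + 1, j, k],
       v[i + 2, j, k], h[1]) +
  lap1(v[i, j - 2, k], v[i, j - 1, k], v[i, j, k], v[i, j + 1, k],
       v[i, j + 2, k], h[2]) +
  lap1(v[i, j, k - 2], v[i, j, k - 1], v[i, j, k], v[i, j, k + 1],
       v[i, j, k + 2], h[3])
}

# brute-force two-sided exact signed-rank p-value by sign enumeration
oracle_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dist <- as.vector(signs %*% r)
  p <- min(1, 2 * min(mean(dist <= V + 1e-9), mean(dist >= V - 1e-9)))
  list(statistic = V, p_value = p)
}
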