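# Shared test utilities.

# Adjusted Rand index between two labelings (independent of label names).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Planted two-group word-vector table: centers along distinct axes
# (between-group cosine 0), small isotropic jitter (within-group cosine
# > 0.9).
planted_two_groups <- function(n_per_group = 10, n_dims = 4, jitter = 0.02,
                               seed = 1) {
  set.seed(seed)
  centers <- diag(n_dims)[1:2, , drop = FALSE]
  v <- centers[rep(1:2, each = n_per_group), ] +
    matrix(rnorm(2 * n_per_group * n_dims, sd = jitter),
           2 * n_per_group, n_dims)
  list(table = word_vector_table(sprintf("w%02d", seq_len(2 * n_per_group)), v),
       labels = rep(1:2, each = n_per_group))
}

# Tiny full-grid example matrix with a single signal voxel carrying one
# semantic dimension.
planted_signal_examples <- function(n = 100, dims = 5, grid = c(5, 4, 3),
                                    signal_voxel = 30, signal_dim = 3,
                                    noise = 0.05, seed = 1) {
  set.seed(seed)
  nv <- prod(grid)
  z <- matrix(rnorm(n * dims), n, dims)
  x <- matrix(rnorm(n * nv), n, nv)
  x[, signal_voxel] <- z[, signal_dim] + rnorm(n, sd = noise)
  geom <- volume_geometry(grid, seq_len(nv))
  list(X = example_matrix(x, sprintf("s%03d", 1:n), geom), Z = z,
       voxel = signal_voxel, dim = signal_dim)
}
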