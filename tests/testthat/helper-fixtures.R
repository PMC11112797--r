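# Small fixtures built in code; everything deterministic under fixed seeds.

# tiny slice with hand-set counts/coords for io tests
tiny_slice <- function() {
  counts <- matrix(c(5, 0, 2,
                     0, 3, 1,
                     4, 4, 0,
                     1, 0, 6), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  slice_data(counts, cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)))
}

# write a slice to tempdir in the MTX layout read_slice expects
write_tiny_files <- function(slice = tiny_slice(), dir = withr::local_tempdir()) {
  write_slice(slice, file.path(dir, "fix"))
}

small_slice <- function(seed = 1, grid = 12L, K = 3L) {
  generate_synthetic_slice(synthetic_spec(
    grid_w = grid, grid_h = grid, n_domains = K, n_genes = 120L,
    markers_per_domain = 10L, log2_effect = 2, seed = seed))
}

# n cells drawn from two orthogonal low-dimensional subspaces (unit-norm
# cells), the premise under which self-representation is block diagonal
two_subspace_data <- function(n = 60, p = 20, r = 3, seed = 0) {
  set.seed(seed)
  U1 <- qr.Q(qr(matrix(rnorm(p * 2 * r), p, 2 * r)))
  U2 <- U1[, (r + 1):(2 * r), drop = FALSE]
  U1 <- U1[, 1:r, drop = FALSE]
  g <- rep(1:2, each = n / 2)
  X <- t(sapply(g, function(k) {
    U <- if (k == 1) U1 else U2
    v <- U %*% rnorm(r)
    v / sqrt(sum(v^2))
  }))
  list(X = X, groups = g)
}
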