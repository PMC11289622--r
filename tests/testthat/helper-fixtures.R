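# Small in-code fixtures shared across test files.

# A tiny deterministic count matrix with dimnames.
toy_counts <- function(n_genes = 6, n_spots = 8, seed = 42, lambda = 20) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_spots, lambda), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("bc%03d", seq_len(n_spots))))
    m
  })
}

# A regular spot grid as a plain tibble.
toy_spots <- function(nr = 10, nc = 10, pitch = 100) {
  g <- expand.grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L)
  tibble::tibble(
    barcode = sprintf("bc%04d", seq_len(nrow(g))),
    x_um = g$col * pitch, y_um = g$row * pitch,
    in_tissue = TRUE, artifact = FALSE
  )
}

# Small spot dataset for DE / normalization tests.
small_dataset <- function(seed = 1, grid = c(10, 10), n_genes = 60,
                          dispersion = 0.02, mean_depth = 2e4, ...) {
  simulate_spot_dataset(
    sim_config(grid_shape = grid, mean_depth = mean_depth,
               dispersion = dispersion, seed = seed, ...),
    gene_panel(n_genes = n_genes)
  )
}

# Independent two-sided binomial enumeration oracle for the Poisson-limit
# exact test: sums dbinom probabilities no larger than the observed one.
binom_twosided_oracle <- function(kA, total, pA) {
  probs <- dbinom(0:total, total, pA)
  p_obs <- probs[kA + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-8)])
}
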