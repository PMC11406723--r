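# Shared fixtures, all built in code at test time.

# A cell_contacts object from 0-based upper-triangle triplets.
# triplets: list(chrom = list(i =, j =, x =))
toy_cell <- function(genome, triplets, cell_id = "cell") {
  mats <- lapply(genome$chrom_names, function(ch) {
    t <- triplets[[ch]]
    if (is.null(t)) t <- list(i = integer(), j = integer(), x = numeric())
    scHiCtype:::triplets_to_symmetric(t$i, t$j, t$x, n_bins(genome, ch))
  })
  names(mats) <- genome$chrom_names
  scHiCtype:::new_cell_contacts(cell_id, mats)
}

# Two well-separated Gaussian clusters in 5 dimensions: a linearly
# separable 2-class embedding fixture (200 cells by default).
separable_embedding <- function(n_per_class = 100, seed = 0) {
  set.seed(seed)
  mu <- rbind(c(3, 3, 0, 0, 0), c(-3, -3, 0, 0, 0))
  X <- rbind(
    matrix(stats::rnorm(n_per_class * 5), ncol = 5) +
      matrix(mu[1, ], n_per_class, 5, byrow = TRUE),
    matrix(stats::rnorm(n_per_class * 5), ncol = 5) +
      matrix(mu[2, ], n_per_class, 5, byrow = TRUE)
  )
  rownames(X) <- sprintf("cell_%03d", seq_len(2 * n_per_class))
  list(X = X, y = rep(c("A", "B"), each = n_per_class))
}

# Small, fast classifier configuration for machinery tests.
fast_config <- function(input_dim, n_classes, ...) {
  model_config(input_dim = input_dim, n_classes = n_classes,
               hidden_sizes = c(16L, 8L), epochs = 60L,
               dropout_rate = 0.2, ...)
}

# Random labeled partition pair generator used by metric oracle tests.
random_partition <- function(n, max_classes, seed) {
  set.seed(seed)
  ka <- sample(2:max_classes, 1)
  kb <- sample(2:max_classes, 1)
  list(a = sample(ka, n, replace = TRUE), b = sample(kb, n, replace = TRUE))
}
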