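#' Toy genome for simulation and tests
#'
#' @param n_chrom Number of chromosomes.
#' @param bins Bins per chromosome.
#' @param resolution Bin width in bp (default 1 Mbp).
#' @return A [genome_spec()] with chromosomes `chr1`, `chr2`, ...
#' @export
toy_genome <- function(n_chrom = 2L, bins = 50L, resolution = 1e6) {
  genome_spec(paste0("chr", seq_len(n_chrom)),
              rep(bins * resolution, n_chrom), resolution = resolution)
}

#' Simulation parameters
#'
#' The generator emulates the statistical structure the pipeline relies on:
#' per-chromosome contact probabilities with genomic distance decay,
#' type-specific enrichment of a few contiguous diagonal blocks
#' (compartment-scale differences between cell types at Mb resolution),
#' very sparse per-cell depth drawn from a negative-binomial-like
#' distribution that straddles the 5,000-contact QC threshold, and
#' optionally imbalanced type frequencies.
#'
#' @param n_types Number of cell types.
#' @param cells_per_type Integer vector of cells per type (length
#'   `n_types`); unequal values give imbalanced datasets.
#' @param genome A [genome_spec()]; default two 50-bin toy chromosomes.
#' @param decay_alpha Distance-decay exponent: baseline contact probability
#'   is proportional to `(1 + |i - j|)^-decay_alpha`.
#' @param block_strength Multiplier applied to each type's enriched blocks;
#'   1 means no type signal at all.
#' @param blocks_per_type Number of enriched contiguous diagonal blocks per
#'   type per chromosome.
#' @param depth_mean Mean per-cell contact count.
#' @param depth_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`).
#' @param seed Master RNG seed; everything downstream is reproducible.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_types = 4L, cells_per_type = rep(50L, n_types),
                       genome = toy_genome(), decay_alpha = 1.0,
                       block_strength = 2.0, blocks_per_type = 3L,
                       depth_mean = 10000, depth_dispersion = 0.3,
                       seed = 1L) {
  stopifnot(n_types >= 1, length(cells_per_type) == n_types,
            all(cells_per_type >= 1), inherits(genome, "genome_spec"),
            decay_alpha >= 0, block_strength > 0, blocks_per_type >= 0,
            depth_mean > 0, depth_dispersion > 0)
  structure(list(n_types = as.integer(n_types),
                 cells_per_type = as.integer(cells_per_type),
                 genome = genome, decay_alpha = decay_alpha,
                 block_strength = block_strength,
                 blocks_per_type = as.integer(blocks_per_type),
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Population contact-probability maps per type
#'
#' Builds, for each cell type and chromosome, a symmetric probability
#' matrix: a shared distance-decay baseline
#' `B_ij = (1 + |i - j|)^-decay_alpha` with `blocks_per_type` seeded random
#' contiguous diagonal blocks multiplied by `block_strength`, normalized so
#' the upper triangle (incl. diagonal) sums to 1.
#'
#' @param p A [sim_params()].
#' @return List (one per type) of named per-chromosome probability
#'   matrices.
#' @export
make_population_maps <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  set.seed(p$seed)
  nb <- n_bins(p$genome)
  lapply(seq_len(p$n_types), function(t) {
    maps <- lapply(p$genome$chrom_names, function(ch) {
      n <- nb[[ch]]
      B <- (1 + abs(outer(seq_len(n), seq_len(n), "-")))^(-p$decay_alpha)
      for (b in seq_len(p$blocks_per_type)) {
        len <- sample(max(2L, n %/% 10L):max(3L, n %/% 5L), 1L)
        start <- sample.int(n - len + 1L, 1L)
        idx <- start:(start + len - 1L)
        B[idx, idx] <- B[idx, idx] * p$block_strength
      }
      ut <- upper.tri(B, diag = TRUE)
      B / sum(B[ut])
    })
    names(maps) <- p$genome$chrom_names
    maps
  })
}

#' Sample one cell from a type's population maps
#'
#' Allocates `depth` contacts across chromosomes proportionally to bin
#' count, then draws each chromosome's contacts multinomially over the
#' upper triangle of its probability map, producing symmetric integer
#' contact matrices with exactly `depth` total contacts.
#'
#' @param type_maps Per-chromosome probability maps for one type, as from
#'   [make_population_maps()].
#' @param depth Total contacts to draw (>= 1).
#' @param genome The matching [genome_spec()].
#' @param cell_id Cell identifier.
#' @return A `cell_contacts` object with `total_contacts == depth`.
#' @export
sample_cell <- function(type_maps, depth, genome, cell_id = "cell") {
  stopifnot(depth >= 1)
  nb <- n_bins(genome)
  w <- nb / sum(nb)
  per_chrom <- as.vector(stats::rmultinom(1L, depth, w))
  mats <- lapply(seq_along(genome$chrom_names), function(ci) {
    ch <- genome$chrom_names[ci]
    n <- nb[[ch]]
    ut <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    probs <- type_maps[[ch]][ut]
    counts <- as.vector(stats::rmultinom(1L, per_chrom[ci], probs))
    keep <- counts > 0
    triplets_to_symmetric(ut[keep, 1] - 1L, ut[keep, 2] - 1L,
                          counts[keep], n)
  })
  names(mats) <- genome$chrom_names
  new_cell_contacts(cell_id, mats)
}

#' Generate a labelled synthetic single-cell Hi-C dataset
#'
#' Draws per-cell depths from a negative binomial (mean `depth_mean`,
#' variance `mu + dispersion * mu^2`, floored at 1), samples each cell from
#' its type's population map, and serializes everything in the formats the
#' pipeline consumes: a 6-column pairs TSV (`cell_id`, `chrom_a`, `pos_a`,
#' `chrom_b`, `pos_b`, `count`, positions at bin midpoints), a standard
#' `chrom.sizes` table, and a labels TSV (`cell_id`, `type`). Byte-identical
#' across runs with the same seed.
#'
#' @param p A [sim_params()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the three file paths (`pairs`, `sizes`,
#'   `labels`), the in-memory `cells`, the `labels` table, the true
#'   `depths`, the population `maps`, and the `genome`.
#' @export
generate_dataset <- function(p, dir) {
  stopifnot(inherits(p, "sim_params"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maps <- make_population_maps(p)    # seeds the RNG with p$seed
  n_cells <- sum(p$cells_per_type)
  types <- rep(paste0("type", seq_len(p$n_types)), p$cells_per_type)
  cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
  depths <- pmax(1, stats::rnbinom(n_cells, mu = p$depth_mean,
                                   size = 1 / p$depth_dispersion))
  type_idx <- rep(seq_len(p$n_types), p$cells_per_type)
  cells <- lapply(seq_len(n_cells), function(i) {
    sample_cell(maps[[type_idx[i]]], depths[i], p$genome, cell_ids[i])
  })
  names(cells) <- cell_ids

  R <- p$genome$resolution
  mid <- floor(R / 2)
  rows <- lapply(cells, function(cell) {
    per_chr <- lapply(names(cell$matrices), function(ch) {
      tri <- methods::as(Matrix::triu(cell$matrices[[ch]]), "TsparseMatrix")
      if (length(tri@x) == 0L) return(NULL)
      ord <- order(tri@i, tri@j)
      data.table::data.table(
        cell_id = cell$cell_id,
        chrom_a = ch, pos_a = as.numeric(tri@i[ord]) * R + mid,
        chrom_b = ch, pos_b = as.numeric(tri@j[ord]) * R + mid,
        count = tri@x[ord])
    })
    data.table::rbindlist(per_chr)
  })
  pairs_path <- file.path(dir, "pairs.tsv")
  sizes_path <- file.path(dir, "chrom.sizes")
  labels_path <- file.path(dir, "labels.tsv")
  data.table::fwrite(data.table::rbindlist(rows), pairs_path,
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::data.table(
    chrom = p$genome$chrom_names,
    length = format(unname(p$genome$chrom_lengths), scientific = FALSE,
                    trim = TRUE)),
    sizes_path, sep = "\t", col.names = FALSE)
  labels <- data.table::data.table(cell_id = cell_ids, type = types)
  data.table::fwrite(labels, labels_path, sep = "\t")
  invisible(list(pairs = pairs_path, sizes = sizes_path,
                 labels_path = labels_path, cells = cells, labels = labels,
                 depths = stats::setNames(depths, cell_ids), maps = maps,
                 genome = p$genome))
}
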