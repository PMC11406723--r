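#' Genome specification for binned Hi-C analysis
#'
#' A genome specification records the chromosomes under analysis, their
#' lengths in base pairs, and the bin width (resolution) used to segment
#' each chromosome into non-overlapping bins. A chromosome of length `L`
#' at resolution `R` has `ceiling(L / R)` bins, so the chromosome tail
#' shorter than one bin width is retained in the final bin.
#'
#' @param chrom_names Character vector of chromosome identifiers, in the
#'   order matrices and embeddings will follow.
#' @param chrom_lengths Numeric vector of chromosome lengths in base pairs,
#'   parallel to `chrom_names`.
#' @param resolution Bin width in base pairs. Default 1 Mbp, the standard
#'   working resolution for sparse single-cell Hi-C maps.
#' @return An object of class `genome_spec`.
#' @examples
#' g <- genome_spec(c("chr1", "chr2"), c(5e7, 3e7))
#' n_bins(g)
#' @export
genome_spec <- function(chrom_names, chrom_lengths, resolution = 1e6) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) == 0L) {
    stop("at least one chromosome is required")
  }
  if (length(chrom_names) != length(chrom_lengths)) {
    stop("chrom_names and chrom_lengths must have the same length")
  }
  if (anyDuplicated(chrom_names)) {
    stop("duplicate chromosome names")
  }
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    stop("resolution must be a single positive number")
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  structure(
    list(
      chrom_names = chrom_names,
      chrom_lengths = stats::setNames(chrom_lengths, chrom_names),
      resolution = as.numeric(resolution)
    ),
    class = "genome_spec"
  )
}

#' Number of bins per chromosome
#'
#' @param genome A [genome_spec()].
#' @param chrom Optional chromosome name(s); defaults to all chromosomes.
#' @return Named integer vector of bin counts, `ceiling(L / R)` per
#'   chromosome.
#' @export
n_bins <- function(genome, chrom = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  if (is.null(chrom)) chrom <- genome$chrom_names
  missing <- setdiff(chrom, genome$chrom_names)
  if (length(missing)) {
    stop("unknown chromosome(s): ", paste(missing, collapse = ", "))
  }
  stats::setNames(as.integer(ceiling(genome$chrom_lengths[chrom] / genome$resolution)),
                  chrom)
}

#' Read a chrom.sizes table
#'
#' Reads the standard two-column, tab-delimited `chrom.sizes` layout
#' (chromosome name, length in bp) and returns a [genome_spec()].
#'
#' @param path Path to the chrom.sizes file.
#' @param resolution Bin width in base pairs (default 1 Mbp).
#' @return A `genome_spec`.
#' @export
read_chrom_sizes <- function(path, resolution = 1e6) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L) stop("chrom.sizes must have two columns (name, length)")
  genome_spec(dt[[1]], as.numeric(dt[[2]]), resolution = resolution)
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosome(s), resolution %s bp\n",
              length(x$chrom_names), format(x$resolution, big.mark = ",")))
  nb <- n_bins(x)
  for (ch in x$chrom_names) {
    cat(sprintf("  %s  length %s  bins %d\n", ch,
                format(x$chrom_lengths[[ch]], big.mark = ",", scientific = FALSE),
                nb[[ch]]))
  }
  invisible(x)
}
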