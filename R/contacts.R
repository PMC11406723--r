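#' Read a single-cell Hi-C pairs table
#'
#' Parses the tab-delimited pairs dialect: `cell_id`, `chrom_a`, `pos_a`,
#' `chrom_b`, `pos_b` and an optional sixth `count` column (default 1).
#' Positions are 1-based base-pair coordinates. Records on chromosomes
#' absent from `genome`, with positions outside `[1, L]`, or with a
#' non-positive count are malformed; the `on_error` policy either skips
#' them with a warning listing offending line numbers, or aborts.
#'
#' @param path Path to the pairs file (plain text or gzip).
#' @param genome A [genome_spec()] used for validation.
#' @param on_error Either `"skip"` (drop malformed records with a warning)
#'   or `"abort"` (stop at the first malformed record).
#' @return A `data.table` with columns `cell_id`, `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`, `count` and one row per valid record. An empty
#'   file yields an empty table.
#' @export
read_pairs <- function(path, genome, on_error = c("skip", "abort")) {
  on_error <- match.arg(on_error)
  stopifnot(inherits(genome, "genome_spec"))
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.table::data.table(
    cell_id = character(), chrom_a = character(), pos_a = numeric(),
    chrom_b = character(), pos_b = numeric(), count = numeric()
  )
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(
    path, header = FALSE, sep = "\t", fill = TRUE, blank.lines.skip = FALSE,
    colClasses = list(character = c(1, 2, 4))
  )
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 5L) {
    stop("pairs file must have at least 5 tab-delimited columns")
  }
  out <- data.table::data.table(
    cell_id = as.character(dt[[1]]),
    chrom_a = as.character(dt[[2]]),
    pos_a   = suppressWarnings(as.numeric(dt[[3]])),
    chrom_b = as.character(dt[[4]]),
    pos_b   = suppressWarnings(as.numeric(dt[[5]])),
    count   = if (ncol(dt) >= 6L) suppressWarnings(as.numeric(dt[[6]])) else 1
  )
  data.table::set(out, which(is.na(out$count)), "count", 1)
  lens <- genome$chrom_lengths
  known_a <- out$chrom_a %in% genome$chrom_names
  known_b <- out$chrom_b %in% genome$chrom_names
  ok <- known_a & known_b &
    is.finite(out$pos_a) & is.finite(out$pos_b) &
    out$pos_a >= 1 & out$pos_b >= 1 &
    is.finite(out$count) & out$count >= 1
  # position upper bounds only checked where the chromosome is known
  ok[ok] <- out$pos_a[ok] <= lens[out$chrom_a[ok]] &
    out$pos_b[ok] <= lens[out$chrom_b[ok]]
  if (!all(ok)) {
    bad <- which(!ok)
    msg <- sprintf("%d malformed record(s) at line(s) %s%s", length(bad),
                   paste(utils::head(bad, 10L), collapse = ", "),
                   if (length(bad) > 10L) ", ..." else "")
    if (on_error == "abort") stop(msg)
    warning(msg, "; skipped")
    out <- out[ok, ]
  }
  out[]
}

#' Bin read pairs into per-cell contact matrices
#'
#' Discards inter-chromosomal records, assigns each position to the 0-based
#' bin `floor((pos - 1) / R)`, and accumulates counts symmetrically into one
#' sparse contact matrix per chromosome per cell (off-diagonal counts appear
#' at both `(i, j)` and `(j, i)`; diagonal counts once). Every cell receives
#' a matrix for every chromosome in `genome`, empty if no pair mapped there.
#'
#' @param pairs A pairs table as returned by [read_pairs()].
#' @param genome A [genome_spec()].
#' @return A named list of `cell_contacts` objects, one per distinct
#'   `cell_id` in order of first appearance.
#' @export
bin_pairs <- function(pairs, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  req <- c("cell_id", "chrom_a", "pos_a", "chrom_b", "pos_b", "count")
  if (!all(req %in% names(pairs))) {
    stop("pairs must contain columns: ", paste(req, collapse = ", "))
  }
  pairs <- data.table::as.data.table(pairs)
  cell_order <- unique(pairs$cell_id)
  R <- genome$resolution
  intra <- pairs[pairs$chrom_a == pairs$chrom_b, ]
  if (nrow(intra)) {
    ba <- floor((intra$pos_a - 1) / R)
    bb <- floor((intra$pos_b - 1) / R)
    trip <- data.table::data.table(
      cell_id = intra$cell_id,
      chrom = intra$chrom_a,
      i = pmin(ba, bb),
      j = pmax(ba, bb),
      count = intra$count
    )
    trip <- trip[, list(count = sum(count)), by = c("cell_id", "chrom", "i", "j")]
  } else {
    trip <- data.table::data.table(cell_id = character(), chrom = character(),
                                   i = integer(), j = integer(), count = numeric())
  }
  cells <- lapply(cell_order, function(cid) {
    sub <- trip[trip$cell_id == cid, ]
    mats <- lapply(genome$chrom_names, function(ch) {
      nb <- n_bins(genome, ch)
      s <- sub[sub$chrom == ch, ]
      triplets_to_symmetric(s$i, s$j, s$count, nb)
    })
    names(mats) <- genome$chrom_names
    new_cell_contacts(cid, mats)
  })
  names(cells) <- cell_order
  cells
}

# Build a symmetric sparse matrix from 0-based upper-triangle triplets.
triplets_to_symmetric <- function(i, j, x, n) {
  if (length(i) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  }
  off <- i != j
  ii <- c(i, j[off]) + 1L
  jj <- c(j, i[off]) + 1L
  xx <- c(x, x[off])
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

new_cell_contacts <- function(cell_id, matrices) {
  structure(
    list(
      cell_id = cell_id,
      matrices = matrices,
      total_contacts = sum(vapply(matrices, upper_tri_sum, numeric(1)))
    ),
    class = "cell_contacts"
  )
}

# Sum of the upper triangle including the diagonal: each read pair counts
# once regardless of the symmetric storage.
upper_tri_sum <- function(m) {
  sum(Matrix::triu(m))
}

#' Total contact count of a cell
#'
#' The per-cell sequencing depth used by quality control: the sum over
#' chromosomes of the upper triangle (including the diagonal) of each
#' contact matrix, so that every read pair contributes once.
#'
#' @param cell A `cell_contacts` object.
#' @return A single non-negative number.
#' @export
total_contacts <- function(cell) {
  stopifnot(inherits(cell, "cell_contacts"))
  sum(vapply(cell$matrices, upper_tri_sum, numeric(1)))
}

#' Cell-level quality control
#'
#' A cell passes when its total contact count is at least `min_contacts`
#' (default 5,000) and every chromosome matrix holds at least one read pair.
#' Cells failing the depth rule get reason code `LOW_DEPTH`; cells with an
#' empty chromosome get `EMPTY_CHROM` (a cell may have both).
#'
#' @param cell A `cell_contacts` object.
#' @param min_contacts Minimum total contacts to keep a cell.
#' @return Logical scalar; attribute `"reasons"` holds the character vector
#'   of reason codes (empty when the cell passes).
#' @export
passes_qc <- function(cell, min_contacts = 5000) {
  stopifnot(inherits(cell, "cell_contacts"))
  reasons <- character()
  if (total_contacts(cell) < min_contacts) reasons <- c(reasons, "LOW_DEPTH")
  empty <- vapply(cell$matrices, function(m) length(m@x) == 0L || all(m@x == 0),
                  logical(1))
  if (any(empty)) reasons <- c(reasons, "EMPTY_CHROM")
  structure(length(reasons) == 0L, reasons = reasons)
}

#' Partition cells by quality control
#'
#' @param cells List of `cell_contacts` objects.
#' @param min_contacts Minimum total contacts to keep a cell.
#' @return A list with `kept` (cells passing QC, input order preserved),
#'   `removed` (the rest), and `reasons` (named list of reason-code vectors
#'   for the removed cells).
#' @export
filter_cells <- function(cells, min_contacts = 5000) {
  if (length(cells) == 0L) {
    return(list(kept = list(), removed = list(), reasons = list()))
  }
  verdicts <- lapply(cells, passes_qc, min_contacts = min_contacts)
  pass <- vapply(verdicts, function(v) isTRUE(as.logical(v)), logical(1))
  reasons <- lapply(verdicts[!pass], attr, "reasons")
  names(reasons) <- vapply(cells[!pass], function(c) c$cell_id, character(1))
  list(kept = cells[pass], removed = cells[!pass], reasons = reasons)
}

#' @export
print.cell_contacts <- function(x, ...) {
  cat(sprintf("cell_contacts %s: %d chromosome(s), %s contacts\n",
              x$cell_id, length(x$matrices),
              format(x$total_contacts, big.mark = ",")))
  invisible(x)
}

#' Save binned contacts as a plain-text container
#'
#' Writes a directory holding `genome.json` (chromosome names, lengths,
#' resolution) and `contacts.tsv` with one row per stored upper-triangle
#' entry: `cell_id`, `chrom`, `i`, `j` (0-based bins, `i <= j`), `count`.
#'
#' @param cells List of `cell_contacts`.
#' @param genome The matching [genome_spec()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
save_contacts <- function(cells, genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(chrom_names = genome$chrom_names,
         chrom_lengths = unname(genome$chrom_lengths),
         resolution = genome$resolution),
    file.path(dir, "genome.json"), auto_unbox = TRUE, digits = NA
  )
  rows <- lapply(cells, function(cell) {
    per_chr <- lapply(names(cell$matrices), function(ch) {
      tri <- methods::as(Matrix::triu(cell$matrices[[ch]]), "TsparseMatrix")
      if (length(tri@x) == 0L) return(NULL)
      ord <- order(tri@i, tri@j)
      data.table::data.table(cell_id = cell$cell_id, chrom = ch,
                             i = tri@i[ord], j = tri@j[ord], count = tri@x[ord])
    })
    data.table::rbindlist(per_chr)
  })
  data.table::fwrite(data.table::rbindlist(rows),
                     file.path(dir, "contacts.tsv"), sep = "\t")
  invisible(dir)
}

#' Load a plain-text contacts container
#'
#' @param dir Directory written by [save_contacts()].
#' @return A list with `cells` (list of `cell_contacts`) and `genome`.
#' @export
load_contacts <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "genome.json"),
                              simplifyVector = TRUE)
  genome <- genome_spec(meta$chrom_names, meta$chrom_lengths, meta$resolution)
  trip <- data.table::fread(file.path(dir, "contacts.tsv"), sep = "\t",
                            colClasses = list(character = c("cell_id", "chrom")))
  cell_order <- unique(trip$cell_id)
  cells <- lapply(cell_order, function(cid) {
    sub <- trip[trip$cell_id == cid, ]
    mats <- lapply(genome$chrom_names, function(ch) {
      s <- sub[sub$chrom == ch, ]
      triplets_to_symmetric(s$i, s$j, s$count, n_bins(genome, ch))
    })
    names(mats) <- genome$chrom_names
    new_cell_contacts(cid, mats)
  })
  names(cells) <- cell_order
  list(cells = cells, genome = genome)
}
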