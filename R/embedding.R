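#' Embedding parameters
#'
#' @param k_chrom Principal components kept per chromosome (default 10).
#' @param k_cell Components of the final, cross-chromosome PCA (default 20).
#' @param scale Also divide features by their standard deviation before the
#'   PCA (columns are always mean-centered; default FALSE).
#' @return An object of class `embed_params`.
#' @export
embed_params <- function(k_chrom = 10L, k_cell = 20L, scale = FALSE) {
  stopifnot(k_chrom >= 1, k_cell >= 1, is.logical(scale))
  structure(list(k_chrom = as.integer(k_chrom), k_cell = as.integer(k_cell),
                 center = TRUE, scale = scale),
            class = "embed_params")
}

#' Flatten one chromosome's matrices across cells into feature rows
#'
#' Each cell's matrix is reduced to its upper triangle including the
#' diagonal, read row-wise, giving `n * (n + 1) / 2` features in a fixed
#' order shared by all cells.
#'
#' @param mats Named list (by cell id) of square matrices with identical
#'   dimensions.
#' @return Numeric matrix, one row per cell (rownames = cell ids).
#' @export
flatten_chrom <- function(mats) {
  if (length(mats) == 0L) stop("no matrices supplied")
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1L ||
      any(vapply(mats, ncol, integer(1)) != dims)) {
    stop("all matrices must be square with identical dimensions")
  }
  n <- dims[[1]]
  # row-wise upper triangle of a symmetric matrix == column-major lower
  # triangle, which R extracts directly
  sel <- lower.tri(matrix(0, n, n), diag = TRUE)
  out <- t(vapply(mats, function(m) as.matrix(m)[sel], numeric(n * (n + 1) / 2)))
  rownames(out) <- names(mats)
  out
}

#' Reconstruct a symmetric matrix from a flattened feature row
#'
#' Inverse of the per-cell flattening used by [flatten_chrom()].
#'
#' @param v Feature vector of length `n * (n + 1) / 2`.
#' @param n Matrix dimension.
#' @return An `n` x `n` symmetric matrix.
#' @export
unflatten_chrom <- function(v, n) {
  if (length(v) != n * (n + 1) / 2) stop("length(v) must equal n*(n+1)/2")
  m <- matrix(0, n, n)
  m[lower.tri(m, diag = TRUE)] <- v
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  m
}

#' Principal component embedding with a deterministic sign convention
#'
#' Column-centers `X` (optionally scales), takes the `k` leading principal
#' components via singular value decomposition, and fixes each component's
#' sign so that its largest-magnitude loading is positive, making results
#' bit-reproducible across runs. The fitted transform (center, scale,
#' rotation) is stored so held-out rows can be projected without refitting.
#'
#' @param X Numeric matrix, rows = cells.
#' @param k Number of components, `1 <= k <= min(nrow(X), ncol(X))`.
#' @param scale Divide columns by their standard deviation (zero-variance
#'   columns are left unscaled).
#' @return An object of class `pca_embedding` with elements `scores`
#'   (`nrow(X)` x `k`, rownames preserved), `rotation`, `center`, `scale_`,
#'   `sdev`, `k`.
#' @export
pca_embed <- function(X, k, scale = FALSE) {
  X <- as.matrix(X)
  M <- nrow(X)
  N <- ncol(X)
  if (M < 2L) stop("need at least 2 rows")
  if (k < 1L || k > min(M, N)) {
    stop(sprintf("k must lie in [1, min(M, N)] = [1, %d]", min(M, N)))
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  scl <- rep(1, N)
  if (scale) {
    s <- apply(Xc, 2L, stats::sd)
    scl <- ifelse(s > 0, s, 1)
    Xc <- sweep(Xc, 2L, scl, "/")
  }
  sv <- svd(Xc, nu = k, nv = k)
  rotation <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i0 <- which.max(abs(rotation[, j]))
    if (rotation[i0, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, rotation = rotation, center = center,
                 scale_ = scl, sdev = sv$d[seq_len(k)] / sqrt(max(M - 1, 1)),
                 k = k),
            class = "pca_embedding")
}

#' Project new rows through a fitted PCA transform
#'
#' @param object A `pca_embedding` from [pca_embed()].
#' @param X New data with the same columns as the fitting matrix.
#' @param ... Unused.
#' @return Score matrix with `object$k` columns.
#' @export
predict.pca_embedding <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$center)) stop("column count mismatch")
  Xc <- sweep(sweep(X, 2L, object$center), 2L, object$scale_, "/")
  scores <- Xc %*% object$rotation
  colnames(scores) <- paste0("PC", seq_len(object$k))
  scores
}

#' Concatenate per-chromosome embeddings
#'
#' Horizontally concatenates per-chromosome score matrices in the given
#' order. Cell order must be identical in every block; mismatches are an
#' error, never silently reordered.
#'
#' @param embeddings Named list of score matrices (or `pca_embedding`
#'   objects), one per chromosome, rows = cells.
#' @return Single matrix, columns grouped by chromosome
#'   (`<chrom>.PC1`, ...).
#' @export
combine_embeddings <- function(embeddings) {
  if (length(embeddings) == 0L) stop("no embeddings supplied")
  blocks <- lapply(embeddings, function(e) {
    if (inherits(e, "pca_embedding")) e$scores else as.matrix(e)
  })
  ids <- rownames(blocks[[1]])
  for (b in blocks) {
    if (!identical(rownames(b), ids)) stop("cell order differs across blocks")
  }
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(names(blocks), function(ch) {
    paste(ch, colnames(blocks[[ch]]), sep = ".")
  }))
  out
}

#' Two-stage PCA cell embedding
#'
#' Stage one embeds each chromosome separately: the imputed matrices of all
#' cells are flattened to upper-triangle feature rows and reduced to
#' `k_chrom` principal components. The per-chromosome scores are then
#' concatenated in genome order and a second PCA reduces them to the final
#' `k_cell`-dimensional cell embedding that feeds the classifier. All fitted
#' transforms are retained so held-out cells can be projected through the
#' identical maps without refitting.
#'
#' @param imputed Named list (by cell id) of per-chromosome imputed matrices,
#'   as returned by [impute_cells()].
#' @param genome A [genome_spec()]; fixes the chromosome order.
#' @param params An [embed_params()] object.
#' @return An object of class `cell_embedder` with elements `embedding`
#'   (cells x `k_cell` matrix), `chrom_pca` (per-chromosome transforms),
#'   `final_pca`, `cell_ids`, `genome`, `params`.
#' @export
embed_cells <- function(imputed, genome, params = embed_params()) {
  stopifnot(inherits(genome, "genome_spec"), inherits(params, "embed_params"))
  if (length(imputed) < 2L) stop("need at least 2 cells")
  chrom_pca <- lapply(genome$chrom_names, function(ch) {
    mats <- lapply(imputed, `[[`, ch)
    X <- flatten_chrom(mats)
    pca_embed(X, k = params$k_chrom, scale = params$scale)
  })
  names(chrom_pca) <- genome$chrom_names
  concat <- combine_embeddings(lapply(chrom_pca, `[[`, "scores"))
  final_pca <- pca_embed(concat, k = params$k_cell, scale = FALSE)
  structure(list(embedding = final_pca$scores,
                 chrom_pca = chrom_pca, final_pca = final_pca,
                 cell_ids = names(imputed), genome = genome, params = params),
            class = "cell_embedder")
}

#' Project held-out cells through a fitted embedder
#'
#' @param embedder A `cell_embedder` from [embed_cells()].
#' @param imputed Named list (by cell id) of per-chromosome imputed matrices
#'   for the new cells.
#' @return Matrix of final embedding coordinates for the new cells.
#' @export
project_cells <- function(embedder, imputed) {
  stopifnot(inherits(embedder, "cell_embedder"))
  genome <- embedder$genome
  blocks <- lapply(genome$chrom_names, function(ch) {
    mats <- lapply(imputed, `[[`, ch)
    stats::predict(embedder$chrom_pca[[ch]], flatten_chrom(mats))
  })
  names(blocks) <- genome$chrom_names
  concat <- combine_embeddings(blocks)
  out <- stats::predict(embedder$final_pca, concat)
  rownames(out) <- names(imputed)
  out
}

#' Write a cell embedding as TSV
#'
#' @param embedding Matrix with cell ids as rownames.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  dt <- data.table::data.table(cell_id = rownames(embedding))
  dt <- cbind(dt, data.table::as.data.table(as.matrix(embedding)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
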