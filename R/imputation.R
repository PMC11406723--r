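#' Imputation parameters
#'
#' Settings for the convolution + random-walk-with-restart imputation that
#' densifies each chromosome's sparse contact matrix before embedding.
#'
#' @param window_pad Half-width of the mean filter; `pad = 1` gives a 3x3
#'   window. `pad = 0` disables smoothing.
#' @param restart_prob Walk-continuation probability `p` in the update
#'   `Q <- p * Q %*% P + (1 - p) * I`; must lie strictly in (0, 1).
#' @param tol Convergence threshold on the maximum row-wise L1 change
#'   between successive iterates.
#' @param max_iter Iteration cap for the random walk.
#' @param top_fraction Fraction of matrix entries kept when binarizing.
#' @param binarize Whether to binarize the imputed matrix, keeping the top
#'   `top_fraction` of entries as 1 and zeroing the rest.
#' @return An object of class `imputation_params`.
#' @export
imputation_params <- function(window_pad = 1L, restart_prob = 0.5,
                              tol = 1e-6, max_iter = 30L,
                              top_fraction = 0.2, binarize = TRUE) {
  stopifnot(window_pad >= 0,
            restart_prob > 0, restart_prob < 1,
            tol > 0, max_iter >= 1,
            top_fraction > 0, top_fraction <= 1,
            is.logical(binarize))
  structure(list(window_pad = as.integer(window_pad),
                 restart_prob = restart_prob, tol = tol,
                 max_iter = as.integer(max_iter),
                 top_fraction = top_fraction, binarize = binarize),
            class = "imputation_params")
}

#' Mean-filter convolution of a contact matrix
#'
#' Replaces each entry by the mean of its `(2 * pad + 1)^2` window. Borders
#' are zero-padded and the divisor is always the full window size, so mass
#' near the edge is attenuated rather than renormalized. Symmetric input
#' gives symmetric output, and the operation is linear.
#'
#' @param mat Square numeric matrix (dense or `Matrix` sparse).
#' @param pad Non-negative integer half-width; `pad = 0` returns the input.
#' @return A dense numeric matrix of the same dimension.
#' @export
conv_smooth <- function(mat, pad = 1L) {
  A <- as.matrix(mat)
  if (nrow(A) != ncol(A)) stop("matrix must be square")
  pad <- as.integer(pad)
  if (pad < 0L) stop("pad must be >= 0")
  if (pad == 0L) return(A)
  n <- nrow(A)
  padded <- matrix(0, n + 2L * pad, n + 2L * pad)
  padded[(pad + 1L):(pad + n), (pad + 1L):(pad + n)] <- A
  out <- matrix(0, n, n)
  for (di in -pad:pad) {
    for (dj in -pad:pad) {
      out <- out + padded[(pad + 1L + di):(pad + n + di),
                          (pad + 1L + dj):(pad + n + dj)]
    }
  }
  out / (2L * pad + 1L)^2
}

#' Random walk with restart on a contact graph
#'
#' Row-normalizes the non-negative input into a transition matrix `P`
#' (all-zero rows become self-loops), then iterates
#' `Q <- p * Q %*% P + (1 - p) * I` from `Q = I` until the maximum row-wise
#' L1 change drops below `tol` or `max_iter` is reached. Because `P` is
#' row-stochastic every iterate is row-stochastic. The fixed point is
#' returned symmetrized as `(Q + t(Q)) / 2` by default, since the iteration
#' itself need not preserve symmetry exactly.
#'
#' @param mat Square non-negative numeric matrix.
#' @param restart_prob Walk-continuation probability `p` in (0, 1).
#' @param tol Convergence threshold on max row-wise L1 change.
#' @param max_iter Iteration cap.
#' @param symmetrize Average the result with its transpose (default TRUE).
#' @param trace Record the maximum deviation of iterate row sums from 1.
#' @return The imputed dense matrix. With `trace = TRUE`, attributes
#'   `"n_iter"` and `"row_sum_dev"` (per-iterate max |rowSum - 1|) are
#'   attached.
#' @export
rwr_impute <- function(mat, restart_prob = 0.5, tol = 1e-6, max_iter = 30L,
                       symmetrize = TRUE, trace = FALSE) {
  A <- as.matrix(mat)
  if (nrow(A) != ncol(A)) stop("matrix must be square")
  if (any(A < 0)) stop("matrix must be non-negative")
  stopifnot(restart_prob > 0, restart_prob < 1)
  n <- nrow(A)
  rs <- rowSums(A)
  P <- A / ifelse(rs > 0, rs, 1)
  zero <- rs == 0
  if (any(zero)) P[zero, ] <- diag(n)[zero, , drop = FALSE]
  I <- diag(n)
  Q <- I
  p <- restart_prob
  dev <- numeric(0)
  iters <- 0L
  for (t in seq_len(max_iter)) {
    Qn <- p * (Q %*% P) + (1 - p) * I
    delta <- max(rowSums(abs(Qn - Q)))
    Q <- Qn
    iters <- t
    if (trace) dev <- c(dev, max(abs(rowSums(Q) - 1)))
    if (delta < tol) break
  }
  if (symmetrize) Q <- (Q + t(Q)) / 2
  if (trace) {
    attr(Q, "n_iter") <- iters
    attr(Q, "row_sum_dev") <- dev
  }
  Q
}

#' Keep the top fraction of matrix entries as 1
#'
#' Ranks all `n^2` entries and sets the top `ceiling(fraction * n^2)` to 1,
#' the rest to 0. Ties at the cutoff are broken deterministically by
#' (row, column) order.
#'
#' @param mat Numeric matrix.
#' @param top_fraction Fraction of entries to keep, in (0, 1].
#' @return A 0/1 matrix of the same dimension.
#' @export
binarize_top <- function(mat, top_fraction = 0.2) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  A <- as.matrix(mat)
  n2 <- length(A)
  m <- ceiling(top_fraction * n2)
  rows <- row(A)
  cols <- col(A)
  ord <- order(-as.vector(A), as.vector(rows), as.vector(cols))
  out <- numeric(n2)
  out[ord[seq_len(m)]] <- 1
  matrix(out, nrow = nrow(A), ncol = ncol(A))
}

#' Impute one cell's contact matrices
#'
#' Per chromosome: mean-filter convolution, random walk with restart, then
#' (optionally) binarization of the top entries. Fully deterministic.
#'
#' @param cell A `cell_contacts` object (normally one that passed QC).
#' @param params An [imputation_params()] object.
#' @return Named list of dense per-chromosome matrices.
#' @export
impute_cell <- function(cell, params = imputation_params()) {
  stopifnot(inherits(cell, "cell_contacts"),
            inherits(params, "imputation_params"))
  lapply(cell$matrices, function(m) {
    x <- conv_smooth(m, params$window_pad)
    x <- rwr_impute(x, restart_prob = params$restart_prob,
                    tol = params$tol, max_iter = params$max_iter)
    if (params$binarize) x <- binarize_top(x, params$top_fraction)
    x
  })
}

#' Impute a collection of cells
#'
#' @param cells List of `cell_contacts`.
#' @param params An [imputation_params()] object.
#' @return Named list (by cell id) of per-chromosome imputed matrices.
#' @export
impute_cells <- function(cells, params = imputation_params()) {
  out <- lapply(cells, impute_cell, params = params)
  names(out) <- vapply(cells, function(c) c$cell_id, character(1))
  out
}

#' Save imputed matrices as a plain-text container
#'
#' Writes `params.json` plus `imputed.tsv` with one row per nonzero entry:
#' `cell_id`, `chrom`, `i`, `j` (0-based), `value`. All nonzero entries are
#' stored (not only the upper triangle) because the binarization tie-break
#' can leave one off-diagonal pair asymmetric.
#'
#' @param imputed Output of [impute_cells()].
#' @param genome The matching [genome_spec()].
#' @param params The [imputation_params()] used.
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
save_imputed <- function(imputed, genome, params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(genome = list(chrom_names = genome$chrom_names,
                       chrom_lengths = unname(genome$chrom_lengths),
                       resolution = genome$resolution),
         params = unclass(params)),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA
  )
  rows <- lapply(names(imputed), function(cid) {
    per_chr <- lapply(names(imputed[[cid]]), function(ch) {
      m <- imputed[[cid]][[ch]]
      keep <- which(m != 0, arr.ind = TRUE)
      if (nrow(keep) == 0L) return(NULL)
      ord <- order(keep[, 1], keep[, 2])
      keep <- keep[ord, , drop = FALSE]
      data.table::data.table(cell_id = cid, chrom = ch,
                             i = keep[, 1] - 1L, j = keep[, 2] - 1L,
                             value = m[keep])
    })
    data.table::rbindlist(per_chr)
  })
  data.table::fwrite(data.table::rbindlist(rows),
                     file.path(dir, "imputed.tsv"), sep = "\t")
  invisible(dir)
}

#' Load imputed matrices from a plain-text container
#'
#' @param dir Directory written by [save_imputed()].
#' @return A list with `imputed`, `genome` and `params`.
#' @export
load_imputed <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  genome <- genome_spec(meta$genome$chrom_names, meta$genome$chrom_lengths,
                        meta$genome$resolution)
  params <- do.call(imputation_params, as.list(meta$params))
  trip <- data.table::fread(file.path(dir, "imputed.tsv"), sep = "\t",
                            colClasses = list(character = c("cell_id", "chrom")))
  cell_order <- unique(trip$cell_id)
  imputed <- lapply(cell_order, function(cid) {
    sub <- trip[trip$cell_id == cid, ]
    mats <- lapply(genome$chrom_names, function(ch) {
      s <- sub[sub$chrom == ch, ]
      nb <- n_bins(genome, ch)
      m <- matrix(0, nb, nb)
      if (nrow(s)) m[cbind(s$i + 1L, s$j + 1L)] <- s$value
      m
    })
    names(mats) <- genome$chrom_names
    mats
  })
  names(imputed) <- cell_order
  list(imputed = imputed, genome = genome, params = params)
}
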