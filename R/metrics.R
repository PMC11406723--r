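#' Contingency table of two labelings
#'
#' Joint counts between two partitions of the same items: entry (r, c) is
#' the number of items with label r in `labels_a` and label c in
#' `labels_b`. The shared substrate for mutual information, NMI and ARI.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Integer matrix with row/column names; attribute `"n"` is the
#'   total item count.
#' @export
contingency <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  if (length(labels_a) == 0L) stop("need at least one item")
  tab <- table(as.character(labels_a), as.character(labels_b))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  structure(counts, n = length(labels_a))
}

#' Mutual information of a contingency table (nats)
#'
#' `sum p(a,b) * log(p(a,b) / (p(a) p(b)))` over nonzero cells, with the
#' convention `0 * log(0) = 0`. Natural logarithm.
#'
#' @param tab A [contingency()] table (any nonnegative count matrix works).
#' @return Non-negative scalar.
#' @export
mutual_information <- function(tab) {
  counts <- unclass(tab)
  n <- sum(counts)
  if (n == 0) stop("empty table")
  p <- counts / n
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log(p[nz] / (pa[nz[, 1]] * pb[nz[, 2]])))
}

#' Shannon entropy of a discrete distribution (nats)
#'
#' `sum p * log(1 / p)` over positive probabilities, with
#' `0 * log(1/0) = 0`.
#'
#' @param p Probability vector (sums to 1 within 1e-9).
#' @return Non-negative scalar.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("negative probability")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information of two labelings
#'
#' `2 * MI / (H(A) + H(B))`, in [0, 1]. When both partitions are trivial
#' (a single class each, so both entropies vanish) the partitions are
#' structurally identical and 1.0 is returned by convention.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar in [0, 1].
#' @export
nmi <- function(labels_a, labels_b) {
  tab <- contingency(labels_a, labels_b)
  n <- attr(tab, "n")
  ha <- shannon_entropy(rowSums(tab) / n)
  hb <- shannon_entropy(colSums(tab) / n)
  if (ha + hb == 0) {
    return(1.0)
  }
  val <- 2 * mutual_information(tab) / (ha + hb)
  min(max(val, 0), 1)
}

#' Adjusted Rand index of two labelings
#'
#' Permutation-model chance-corrected pair-counting agreement
#' (Hubert-Arabie): `(Index - E[Index]) / (Max - E[Index])` over the
#' contingency table's pair counts. A degenerate denominator (e.g. both
#' partitions trivial, or both all-singleton) means perfect agreement and
#' returns 1.0.
#'
#' @param labels_a,labels_b Equal-length label vectors (n >= 2).
#' @return Scalar in [-1, 1]; 1 for identical partitions, ~0 for random.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) < 2L) stop("need at least 2 items")
  tab <- contingency(labels_a, labels_b)
  n <- attr(tab, "n")
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(unclass(tab)))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (abs(maximum - expected) < .Machine$double.eps * 4 * max(1, maximum)) {
    return(1.0)
  }
  (sum_ij - expected) / (maximum - expected)
}

#' One-vs-rest confusion counts
#'
#' TP/FP/TN/FN for one class treated as positive against all others.
#'
#' @param labels_true,labels_pred Equal-length label vectors.
#' @param positive_class The class scored as positive; must occur in the
#'   union of both label sets.
#' @return Named list with `TP`, `FP`, `TN`, `FN` (summing to n).
#' @export
confusion <- function(labels_true, labels_pred, positive_class) {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors differ in length")
  }
  pool <- union(as.character(labels_true), as.character(labels_pred))
  if (!positive_class %in% pool) stop("unknown class: ", positive_class)
  tp <- as.character(labels_true) == positive_class
  pp <- as.character(labels_pred) == positive_class
  list(TP = sum(tp & pp), FP = sum(!tp & pp),
       TN = sum(!tp & !pp), FN = sum(tp & !pp))
}

#' True- and false-positive rates
#'
#' `TPR = TP / (TP + FN)` and `FPR = FP / (TN + FP)`. An empty denominator
#' yields 0 with a warning.
#'
#' @param counts Confusion counts from [confusion()].
#' @return Named numeric vector `c(tpr, fpr)`.
#' @export
tpr_fpr <- function(counts) {
  tpr <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN) else {
    warning("no positive instances; TPR set to 0")
    0
  }
  fpr <- if (counts$TN + counts$FP > 0) counts$FP / (counts$TN + counts$FP) else {
    warning("no negative instances; FPR set to 0")
    0
  }
  c(tpr = tpr, fpr = fpr)
}

#' ROC curve and AUC for a binary problem
#'
#' Sweeps every distinct score as a threshold (descending, ties collapsed),
#' accumulating TPR/FPR from (0, 0) to (1, 1); the area under the curve is
#' integrated by the trapezoid rule, which under ties equals the
#' tie-corrected Mann-Whitney statistic.
#'
#' @param scores Numeric score per instance (larger = more positive).
#' @param labels_positive Logical (or coercible) indicator of the positive
#'   class; both classes must be present.
#' @return An object of class `roc_curve`: `thresholds` (descending,
#'   starting at `Inf`), aligned `fpr` and `tpr`, and `auc`.
#' @export
roc_auc <- function(scores, labels_positive) {
  y <- as.logical(labels_positive)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  if (any(is.na(scores)) || any(is.na(y))) stop("NA in scores or labels")
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  tps <- cumsum(y)
  fps <- cumsum(!y)
  last <- which(diff(s) != 0)          # collapse threshold ties
  idx <- c(last, length(s))
  tpr <- c(0, tps[idx] / n_pos)
  fpr <- c(0, fps[idx] / n_neg)
  thresholds <- c(Inf, s[idx])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' Macro-averaged one-vs-rest AUC
#'
#' One ROC per class present in `labels_true` (that class's score column
#' against an is-that-class indicator), averaged with equal class weights.
#'
#' @param score_matrix Instances x classes score matrix with class
#'   colnames.
#' @param labels_true True labels; every class present must have a score
#'   column.
#' @return Macro-average AUC in [0, 1].
#' @export
macro_auc <- function(score_matrix, labels_true) {
  labels_true <- as.character(labels_true)
  classes <- sort(unique(labels_true))
  if (length(classes) < 2L) stop("need at least 2 classes")
  missing <- setdiff(classes, colnames(score_matrix))
  if (length(missing)) stop("no score column for class: ",
                            paste(missing, collapse = ", "))
  aucs <- vapply(classes, function(cl) {
    roc_auc(score_matrix[, cl], labels_true == cl)$auc
  }, numeric(1))
  mean(aucs)
}

#' Classification accuracy
#'
#' @param labels_true,labels_pred Equal-length label vectors.
#' @return Fraction of exact matches, in [0, 1].
#' @export
accuracy <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors differ in length")
  }
  mean(as.character(labels_true) == as.character(labels_pred))
}

#' Seeded k-fold partition
#'
#' Randomly assigns `n` items to `k` disjoint, exhaustive folds whose sizes
#' differ by at most one. With `stratify`, the assignment is done per class
#' so class proportions are approximately preserved in every fold.
#'
#' @param n Number of items (`n >= k`).
#' @param k Number of folds.
#' @param seed RNG seed.
#' @param stratify Optional label vector of length `n`.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(n, k, seed = 1L, stratify = NULL) {
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k must not exceed n")
  set.seed(seed)
  fold <- integer(n)
  if (is.null(stratify)) {
    fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
  } else {
    if (length(stratify) != n) stop("stratify must have length n")
    offset <- 0L
    for (cl in unique(as.character(stratify))) {
      idx <- which(as.character(stratify) == cl)
      ids <- (offset + seq_along(idx) - 1L) %% k + 1L
      fold[idx[sample.int(length(idx))]] <- ids
      offset <- offset + length(idx)
    }
  }
  fold
}

#' K-fold cross-validation of a classifier
#'
#' Partitions the cells into `k` seeded folds, trains on the other `k - 1`
#' folds and scores accuracy on the held-out fold, `k` times; the mean fold
#' accuracy is the cross-validation score.
#'
#' @param X Feature matrix, one row per cell.
#' @param labels Label vector.
#' @param trainer Function `(X_train, labels_train) -> model` whose result
#'   works with [predict()]; defaults to [train_mlp()] with `config`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment (and, via `config`, training).
#' @param stratified Preserve class proportions across folds.
#' @param config A [model_config()] used by the default trainer.
#' @return A list with `fold_acc` (length `k`), `mean_acc`, and `folds`
#'   (the fold id of every cell).
#' @export
kfold_cv <- function(X, labels, trainer = NULL, k = 10L, seed = 1L,
                     stratified = FALSE, config = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  if (length(labels) != n) stop("labels must match rows of X")
  if (is.null(trainer)) {
    if (is.null(config)) stop("supply a trainer or a model config")
    trainer <- function(Xtr, ytr) train_mlp(Xtr, ytr, config)
  }
  folds <- make_folds(n, k, seed = seed,
                      stratify = if (stratified) labels else NULL)
  fold_acc <- vapply(seq_len(k), function(f) {
    te <- folds == f
    model <- trainer(X[!te, , drop = FALSE], labels[!te])
    accuracy(labels[te], predict(model, X[te, , drop = FALSE]))
  }, numeric(1))
  list(fold_acc = fold_acc, mean_acc = mean(fold_acc), folds = folds)
}

#' Full evaluation report
#'
#' Computes the package's standard evaluation block for a set of
#' predictions: accuracy, ARI, NMI, per-class TPR/FPR, and (when a score
#' matrix is supplied) macro one-vs-rest AUC.
#'
#' @param labels_true True labels.
#' @param labels_pred Predicted labels.
#' @param scores Optional score matrix with class colnames for AUC.
#' @return A list: `acc`, `ari`, `nmi`, `auc` (or `NA`), `per_class`
#'   (data frame of TP/FP/TN/FN/TPR/FPR per class).
#' @export
evaluate_predictions <- function(labels_true, labels_pred, scores = NULL) {
  classes <- sort(unique(as.character(labels_true)))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    cc <- confusion(labels_true, labels_pred, cl)
    rates <- suppressWarnings(tpr_fpr(cc))
    data.frame(class = cl, TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
               tpr = rates[["tpr"]], fpr = rates[["fpr"]])
  }))
  auc <- if (!is.null(scores) && length(classes) >= 2L) {
    macro_auc(scores, labels_true)
  } else {
    NA_real_
  }
  list(acc = accuracy(labels_true, labels_pred),
       ari = ari(labels_true, labels_pred),
       nmi = nmi(labels_true, labels_pred),
       auc = auc, per_class = per_class)
}

#' Write an evaluation report
#'
#' @param report Output of [evaluate_predictions()] (optionally with extra
#'   scalar entries such as CV accuracy).
#' @param path_json,path_tsv Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_metrics_report <- function(report, path_json = NULL, path_tsv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(report, path_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(path_tsv)) {
    scalars <- report[vapply(report, function(x)
      is.atomic(x) && length(x) == 1L, logical(1))]
    dt <- data.table::data.table(metric = names(scalars),
                                 value = unlist(scalars, use.names = FALSE))
    data.table::fwrite(dt, path_tsv, sep = "\t")
  }
  invisible(report)
}
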