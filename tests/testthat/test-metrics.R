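test_that("contingency tables count joint labels with correct marginals", {
  t1 <- contingency(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unclass(t1), diag(c(2L, 2L)), ignore_attr = TRUE)
  t2 <- contingency(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(unclass(t2), matrix(1L, 2, 2), ignore_attr = TRUE)
  expect_error(contingency(1:3, 1:4), "length")

  set.seed(6)
  a <- sample(letters[1:4], 50, replace = TRUE)
  b <- sample(1:3, 50, replace = TRUE)
  tab <- contingency(a, b)
  expect_equal(rowSums(tab), as.vector(table(a)), ignore_attr = TRUE)
  expect_equal(colSums(tab), as.vector(table(b)), ignore_attr = TRUE)
  expect_equal(attr(tab, "n"), 50L)
})

test_that("mutual information and entropy follow the defining formulas", {
  expect_equal(mutual_information(contingency(c(0, 0, 1, 1), c(0, 1, 0, 1))), 0)
  expect_equal(mutual_information(contingency(c(0, 0, 1, 1), c(0, 0, 1, 1))),
               log(2))

  expect_equal(shannon_entropy(1), 0)                 # point mass
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  for (k in c(3, 5, 8)) {
    expect_equal(shannon_entropy(rep(1 / k, k)), log(k))
  }
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")

  # information inequality: MI <= min(H(A), H(B))
  set.seed(8)
  for (rep in 1:20) {
    pp <- random_partition(60, 5, seed = rep)
    tab <- contingency(pp$a, pp$b)
    n <- attr(tab, "n")
    expect_lte(mutual_information(tab),
               min(shannon_entropy(rowSums(tab) / n),
                   shannon_entropy(colSums(tab) / n)) + 1e-12)
  }
})

test_that("NMI hits its anchor cases and is symmetric and relabel-invariant", {
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0.0)
  expect_equal(nmi(rep("a", 5), rep("b", 5)), 1.0)   # both trivial

  for (rep in 1:20) {
    pp <- random_partition(40, 4, seed = 100 + rep)
    expect_equal(nmi(pp$a, pp$b), nmi(pp$b, pp$a), tolerance = 1e-12)
    relab <- c("p", "q", "r", "s", "t", "u")[pp$a]
    expect_equal(nmi(pp$a, pp$b), nmi(relab, pp$b), tolerance = 1e-12)
    expect_gte(nmi(pp$a, pp$b), 0)
    expect_lte(nmi(pp$a, pp$b), 1)
  }
})

test_that("ARI matches exhaustive pair counting and is chance-centered", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  expect_equal(ari(c("x", "x", "y"), c("a", "a", "b")), 1.0)

  # brute-force oracle over all C(n,2) pairs
  ari_oracle <- function(a, b) {
    n <- length(a)
    idx <- utils::combn(n, 2)
    sa <- a[idx[1, ]] == a[idx[2, ]]
    sb <- b[idx[1, ]] == b[idx[2, ]]
    n11 <- sum(sa & sb); n00 <- sum(!sa & !sb)
    n10 <- sum(sa & !sb); n01 <- sum(!sa & sb)
    npairs <- ncol(idx)
    exp_idx <- (n11 + n10) * (n11 + n01) / npairs
    max_idx <- ((n11 + n10) + (n11 + n01)) / 2
    (n11 - exp_idx) / (max_idx - exp_idx)
  }
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)),
               ari_oracle(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  for (rep in 1:20) {
    pp <- random_partition(30, 5, seed = 200 + rep)
    expect_equal(ari(pp$a, pp$b), ari_oracle(pp$a, pp$b), tolerance = 1e-12)
    relab <- letters[pp$a]
    expect_equal(ari(pp$a, pp$b), ari(relab, pp$b), tolerance = 1e-12)
    expect_lte(abs(ari(pp$a, pp$b)), 1)
  }

  # expected ARI of random vs random partitions is ~0
  set.seed(9)
  vals <- replicate(1000, {
    ari(sample(4, 100, replace = TRUE), sample(4, 100, replace = TRUE))
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("confusion counts and TPR/FPR follow their definitions", {
  truth <- c("a", "a", "b", "b", "b")
  perfect <- confusion(truth, truth, "a")
  expect_equal(perfect$FP + perfect$FN, 0)

  all_pos <- confusion(truth, rep("a", 5), "a")
  expect_equal(all_pos$TN + all_pos$FN, 0)
  expect_error(confusion(truth, truth, "zz"), "unknown class")

  set.seed(10)
  t30 <- sample(c("a", "b", "c"), 30, replace = TRUE)
  p30 <- sample(c("a", "b", "c"), 30, replace = TRUE)
  cc <- confusion(t30, p30, "b")
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 30)

  expect_equal(unname(tpr_fpr(list(TP = 8, FN = 2, FP = 0, TN = 5))),
               c(0.8, 0))
  expect_equal(unname(tpr_fpr(list(TP = 3, FN = 1, FP = 2, TN = 4))),
               c(0.75, 1 / 3))
  expect_warning(z <- tpr_fpr(list(TP = 0, FN = 0, FP = 1, TN = 1)),
                 "no positive")
  expect_equal(unname(z[1]), 0)
})

test_that("ROC curves are monotone with correct anchors and match pROC", {
  sep <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1.0)
  flat <- roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(flat$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")

  set.seed(12)
  for (rep in 1:10) {
    s <- round(runif(40), 2)               # rounded scores force ties
    y <- runif(40) > 0.4
    if (!any(y) || all(y)) next
    r <- roc_auc(s, y)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    expect_equal(r$fpr[1], 0)
    expect_equal(r$tpr[length(r$tpr)], 1)
    expect_gte(r$auc, 0)
    expect_lte(r$auc, 1)
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(r$auc,
                   as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-10)
    }
  }
})

test_that("macro AUC averages one-vs-rest AUCs over the observed classes", {
  truth <- c("a", "a", "b", "b")
  scores <- rbind(c(0.9, 0.1), c(0.8, 0.3), c(0.2, 0.7), c(0.3, 0.6))
  colnames(scores) <- c("a", "b")
  expect_equal(macro_auc(scores, truth), 1.0)
  expect_error(macro_auc(scores[, 1, drop = FALSE], truth), "no score column")
})

test_that("fold assignment partitions items with near-equal sizes", {
  f <- make_folds(10, 10, seed = 1)        # leave-one-out
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 1))
  expect_error(make_folds(5, 6), "exceed")

  # stratified folds keep every class spread across folds
  y <- rep(c("a", "b"), c(30, 10))
  fs <- make_folds(40, 5, seed = 2, stratify = y)
  expect_true(all(table(fs[y == "a"]) == 6))
  expect_true(all(table(fs[y == "b"]) == 2))
})

test_that("k-fold CV machinery trains per fold and averages accuracy", {
  # nearest-centroid trainer: fast, deterministic, package-independent path
  nc_trainer <- function(X, y) {
    structure(list(mu = do.call(rbind, lapply(split(as.data.frame(X), y),
                                              colMeans)),
                   classes = sort(unique(y))),
              class = "nc_model")
  }
  assign("predict.nc_model",
         function(object, X, ...) {
           d <- as.matrix(dist(rbind(object$mu, X)))
           k <- nrow(object$mu)
           object$classes[apply(d[-(1:k), 1:k, drop = FALSE], 1, which.min)]
         },
         envir = globalenv())
  on.exit(rm("predict.nc_model", envir = globalenv()), add = TRUE)
  fix <- separable_embedding(25, seed = 6)
  cv <- kfold_cv(fix$X, fix$y, trainer = nc_trainer, k = 5, seed = 6)
  expect_length(cv$fold_acc, 5L)
  expect_equal(cv$mean_acc, mean(cv$fold_acc))
  expect_gte(cv$mean_acc, 0.95)
  expect_equal(sort(unique(cv$folds)), 1:5)
})

test_that("accuracy and the evaluation report behave on plain cases", {
  expect_equal(accuracy(1:4, 1:4), 1.0)
  expect_equal(accuracy(1:4, 5:8), 0.0)
  expect_equal(accuracy(c(1, 2, 3, 4), c(1, 2, 3, 9)), 0.75)

  truth <- c("a", "a", "b", "b", "c", "c")
  pred <- c("a", "a", "b", "c", "c", "c")
  scores <- matrix(runif(18), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  rep_ <- evaluate_predictions(truth, pred, scores)
  expect_equal(rep_$acc, 5 / 6)
  expect_equal(nrow(rep_$per_class), 3L)
  expect_true(is.finite(rep_$auc))
  # metrics stay finite on heavily imbalanced labelings
  imb_t <- rep(c("t1", "t2", "t3", "t4"), c(45, 746, 1759, 111) %/% 10)
  set.seed(13)
  imb_p <- sample(imb_t)
  expect_true(is.finite(ari(imb_t, imb_p)))
  expect_true(is.finite(nmi(imb_t, imb_p)))
})
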