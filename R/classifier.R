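#' Network configuration
#'
#' Hyperparameters of the feed-forward cell-type classifier: two hidden
#' layers with rectified-linear activations, dropout regularization on the
#' hidden activations, and a per-class sigmoid output trained against
#' one-hot targets with elementwise binary cross-entropy (a softmax /
#' categorical cross-entropy switch is provided). Dropout defaults to 0.5,
#' the rate at which held-out agreement scores peak in practice on sparse
#' single-cell Hi-C embeddings.
#'
#' @param input_dim Number of input features (embedding dimension).
#' @param n_classes Number of cell types (>= 2).
#' @param hidden_sizes Integer vector of the two hidden-layer widths.
#' @param dropout_rate Fraction of hidden units dropped during training,
#'   in [0, 1). Inverted scaling is used, so inference needs no rescale.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Gradient-descent step size.
#' @param momentum Classical momentum coefficient.
#' @param val_fraction Fraction of training cells held out for the
#'   validation curve and early stopping (0 disables both).
#' @param early_stop_patience Epochs without validation-loss improvement
#'   tolerated before training stops (best weights are restored).
#' @param loss `"sigmoid_bce"` (default) or `"softmax_ce"`.
#' @param standardize Z-score the input features using statistics of the
#'   training data (stored in the model and reapplied at prediction).
#' @param seed Single integer seeding weight initialization, batch
#'   shuffling, the validation split and dropout masks.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_dim, n_classes,
                         hidden_sizes = c(256L, 64L),
                         dropout_rate = 0.5,
                         epochs = 100L, batch_size = 32L,
                         learning_rate = 1e-2, momentum = 0.9,
                         val_fraction = 0.1, early_stop_patience = 10L,
                         loss = c("sigmoid_bce", "softmax_ce"),
                         standardize = TRUE, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(input_dim >= 1, n_classes >= 2,
            length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
            dropout_rate >= 0, dropout_rate < 1,
            epochs >= 0, batch_size >= 1,
            learning_rate > 0, momentum >= 0, momentum < 1,
            val_fraction >= 0, val_fraction < 1,
            early_stop_patience >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 val_fraction = val_fraction,
                 early_stop_patience = as.integer(early_stop_patience),
                 loss = loss, standardize = standardize,
                 seed = as.integer(seed)),
            class = "model_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Seeded scaled-uniform initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
init_layers <- function(config) {
  dims <- c(config$input_dim, config$hidden_sizes, config$n_classes)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    lim <- 1 / sqrt(fan_in)
    W <- matrix(stats::runif(fan_in * dims[l + 1L], -lim, lim),
                nrow = fan_in)
    layers[[l]] <- list(W = W, b = rep(0, dims[l + 1L]))
  }
  layers
}

new_mlp <- function(layers, config, classes, feat_center, feat_scale,
                    history = NULL) {
  structure(list(layers = layers, config = config, classes = classes,
                 feat_center = feat_center, feat_scale = feat_scale,
                 history = history),
            class = "schic_mlp")
}

standardize_input <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$config$input_dim) {
    stop(sprintf("expected %d input features, got %d",
                 model$config$input_dim, ncol(X)))
  }
  if (!is.null(model$feat_center)) {
    X <- sweep(sweep(X, 2L, model$feat_center), 2L, model$feat_scale, "/")
  }
  X
}

#' Forward pass of the classifier
#'
#' Hidden layers apply an affine map followed by ReLU; the output layer
#' applies an affine map followed by an elementwise sigmoid (or softmax,
#' per the configured loss), so every score lies in (0, 1). Dropout is
#' active only in training mode, with inverted scaling: kept activations
#' are divided by the keep probability so the evaluation pass needs no
#' adjustment.
#'
#' @param model A `schic_mlp`.
#' @param X Input matrix, one row per cell.
#' @param train_mode Apply dropout masks (draws from the current RNG).
#' @return Score matrix with one column per class.
#' @export
forward <- function(model, X, train_mode = FALSE) {
  mlp_forward(model, X, train_mode = train_mode)$out
}

# Forward pass keeping per-layer caches for backpropagation.
mlp_forward <- function(model, X, train_mode = FALSE) {
  X <- standardize_input(model, X)
  layers <- model$layers
  L <- length(layers)
  rate <- if (train_mode) model$config$dropout_rate else 0
  H <- X
  Zs <- vector("list", L)
  As <- vector("list", L + 1L)
  masks <- vector("list", L)
  As[[1L]] <- H
  for (l in seq_len(L - 1L)) {
    Z <- H %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(H), length(layers[[l]]$b), byrow = TRUE)
    A <- pmax(Z, 0)
    if (rate > 0) {
      mask <- (matrix(stats::runif(length(A)), nrow(A)) >= rate) / (1 - rate)
      A <- A * mask
      masks[[l]] <- mask
    }
    Zs[[l]] <- Z
    As[[l + 1L]] <- A
    H <- A
  }
  Zout <- H %*% layers[[L]]$W +
    matrix(layers[[L]]$b, nrow(H), length(layers[[L]]$b), byrow = TRUE)
  out <- if (model$config$loss == "softmax_ce") {
    e <- exp(Zout - apply(Zout, 1L, max))
    e / rowSums(e)
  } else {
    sigmoid(Zout)
  }
  Zs[[L]] <- Zout
  list(out = out, Zs = Zs, As = As, masks = masks)
}

# Mean loss over the batch. sigmoid_bce averages the elementwise binary
# cross-entropy over all M*K entries; softmax_ce averages the categorical
# cross-entropy over the M rows.
mlp_loss <- function(scores, Y, loss) {
  eps <- 1e-12
  s <- pmin(pmax(scores, eps), 1 - eps)
  if (loss == "softmax_ce") {
    -mean(rowSums(Y * log(s)))
  } else {
    -mean(Y * log(s) + (1 - Y) * log(1 - s))
  }
}

# Analytic gradients of the mean loss for one batch. For both losses the
# output-layer error simplifies to (scores - Y) / normalizer.
mlp_gradients <- function(model, X, Y, cache = NULL, train_mode = FALSE) {
  if (is.null(cache)) cache <- mlp_forward(model, X, train_mode = train_mode)
  layers <- model$layers
  L <- length(layers)
  M <- nrow(cache$out)
  K <- ncol(cache$out)
  norm <- if (model$config$loss == "softmax_ce") M else M * K
  dZ <- (cache$out - Y) / norm
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(cache$As[[l]], dZ), b = colSums(dZ))
    if (l > 1L) {
      dA <- dZ %*% t(layers[[l]]$W)
      if (!is.null(cache$masks[[l - 1L]])) dA <- dA * cache$masks[[l - 1L]]
      dZ <- dA * (cache$Zs[[l - 1L]] > 0)
    }
  }
  grads
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  Y
}

#' Train the cell-type classifier
#'
#' Minimizes the configured loss between the network's scores and one-hot
#' targets by mini-batch gradient descent with classical momentum. A
#' seeded validation split tracks generalization each epoch; training
#' stops early when the validation loss has not improved for
#' `early_stop_patience` epochs and the best-validation weights are
#' restored. Every source of randomness (weight initialization, the
#' validation split, batch shuffling, dropout masks) flows from
#' `config$seed`, so identical calls give identical weights.
#'
#' @param X Embedding matrix, one row per cell.
#' @param labels Cell-type labels (factor or character), one per row.
#' @param config A [model_config()]; its `input_dim`/`n_classes` must match
#'   the data.
#' @return A `schic_mlp` with learned weights, the class vocabulary, the
#'   feature standardization, and a per-epoch `history` data frame
#'   (train/validation loss and accuracy).
#' @export
train_mlp <- function(X, labels, config) {
  stopifnot(inherits(config, "model_config"))
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("labels must match rows of X")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("labels must cover at least 2 classes")
  if (length(classes) != config$n_classes) {
    stop(sprintf("config declares %d classes but labels contain %d",
                 config$n_classes, length(classes)))
  }
  if (ncol(X) != config$input_dim) {
    stop(sprintf("config declares input_dim %d but X has %d columns",
                 config$input_dim, ncol(X)))
  }
  set.seed(config$seed)
  feat_center <- NULL
  feat_scale <- NULL
  if (config$standardize) {
    feat_center <- colMeans(X)
    s <- apply(X, 2L, stats::sd)
    feat_scale <- ifelse(is.finite(s) & s > 0, s, 1)
  }
  model <- new_mlp(init_layers(config), config, classes,
                   feat_center, feat_scale)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  if (config$epochs == 0L) {
    model$history <- history
    return(model)
  }
  M <- nrow(X)
  n_val <- floor(config$val_fraction * M)
  val_idx <- if (n_val >= 1L) sample.int(M, n_val) else integer()
  tr_idx <- setdiff(seq_len(M), val_idx)
  if (length(tr_idx) < 2L) stop("too few cells left for training")
  Y <- one_hot(labels, classes)
  Xtr <- X[tr_idx, , drop = FALSE]
  Ytr <- Y[tr_idx, , drop = FALSE]
  ytr <- labels[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]
  Yval <- Y[val_idx, , drop = FALSE]
  yval <- labels[val_idx]

  vel <- lapply(model$layers, function(l) {
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = rep(0, length(l$b)))
  })
  best <- list(loss = Inf, layers = model$layers, stale = 0L)
  lr <- config$learning_rate
  mom <- config$momentum
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(tr_idx))
    starts <- seq(1L, length(ord), by = config$batch_size)
    for (s0 in starts) {
      bidx <- ord[s0:min(s0 + config$batch_size - 1L, length(ord))]
      cache <- mlp_forward(model, Xtr[bidx, , drop = FALSE], train_mode = TRUE)
      grads <- mlp_gradients(model, NULL, Ytr[bidx, , drop = FALSE],
                             cache = cache)
      for (l in seq_along(model$layers)) {
        vel[[l]]$W <- mom * vel[[l]]$W - lr * grads[[l]]$W
        vel[[l]]$b <- mom * vel[[l]]$b - lr * grads[[l]]$b
        model$layers[[l]]$W <- model$layers[[l]]$W + vel[[l]]$W
        model$layers[[l]]$b <- model$layers[[l]]$b + vel[[l]]$b
      }
    }
    tr_scores <- forward(model, Xtr)
    tr_loss <- mlp_loss(tr_scores, Ytr, config$loss)
    if (!is.finite(tr_loss)) {
      stop(sprintf("non-finite training loss at epoch %d; reduce the learning rate",
                   epoch))
    }
    tr_acc <- mean(classes[max.col(tr_scores, ties.method = "first")] == ytr)
    if (length(val_idx)) {
      val_scores <- forward(model, Xval)
      val_loss <- mlp_loss(val_scores, Yval, config$loss)
      val_acc <- mean(classes[max.col(val_scores, ties.method = "first")] == yval)
    } else {
      val_loss <- NA_real_
      val_acc <- NA_real_
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tr_loss, train_acc = tr_acc,
      val_loss = val_loss, val_acc = val_acc))
    if (length(val_idx)) {
      if (val_loss < best$loss - 1e-12) {
        best$loss <- val_loss
        best$layers <- model$layers
        best$stale <- 0L
      } else {
        best$stale <- best$stale + 1L
        if (best$stale >= config$early_stop_patience) {
          model$layers <- best$layers
          break
        }
      }
    }
  }
  if (length(val_idx) && is.finite(best$loss)) model$layers <- best$layers
  model$history <- history
  model
}

#' Class scores for new cells
#'
#' Raw per-class sigmoid (or softmax) scores from an evaluation-mode
#' forward pass; sigmoid scores are not renormalized across classes.
#'
#' @param model A trained `schic_mlp`.
#' @param X Embedding matrix.
#' @return Matrix of scores in (0, 1), one column per class.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "schic_mlp"))
  scores <- forward(model, X, train_mode = FALSE)
  colnames(scores) <- model$classes
  rownames(scores) <- rownames(X)
  scores
}

#' Predict cell-type labels
#'
#' Argmax over the class scores; exact ties are resolved in favor of the
#' earlier class in the model's vocabulary.
#'
#' @param object A trained `schic_mlp`.
#' @param X Embedding matrix.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.schic_mlp <- function(object, X, ...) {
  scores <- predict_proba(object, X)
  object$classes[max.col(scores, ties.method = "first")]
}

#' @export
print.schic_mlp <- function(x, ...) {
  dims <- c(x$config$input_dim, x$config$hidden_sizes, x$config$n_classes)
  cat(sprintf("schic_mlp: %s, dropout %.2f, loss %s, classes: %s\n",
              paste(dims, collapse = "-"), x$config$dropout_rate,
              x$config$loss, paste(x$classes, collapse = ", ")))
  if (!is.null(x$history) && nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epoch(s); final train loss %.4f acc %.3f\n",
                nrow(x$history), last$train_loss, last$train_acc))
  }
  invisible(x)
}

#' Save / load a trained model
#'
#' Serializes the full model (weights, configuration, class vocabulary,
#' feature standardization, training history); reloading reproduces
#' predictions bit-exactly.
#'
#' @param model A `schic_mlp`.
#' @param path Destination file.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "schic_mlp"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "schic_mlp")) stop("not a saved schic_mlp")
  model
}

#' Sweep the dropout rate
#'
#' Trains one model per dropout rate on a fixed seeded train/test split of
#' the supplied cells and scores the held-out predictions with ARI, NMI and
#' accuracy — the diagnostic used to choose the dropout default.
#'
#' @param X Embedding matrix.
#' @param labels Cell-type labels.
#' @param rates Dropout rates to evaluate (0.5 included by default).
#' @param config Base [model_config()]; its `dropout_rate` is overridden.
#' @param test_fraction Held-out fraction of cells (seeded by
#'   `config$seed`).
#' @return `data.frame` with columns `rate`, `ari`, `nmi`, `acc`.
#' @export
dropout_sweep <- function(X, labels, rates = c(0, 0.2, 0.5, 0.8),
                          config, test_fraction = 0.3) {
  stopifnot(all(rates >= 0), all(rates < 1))
  X <- as.matrix(X)
  labels <- as.character(labels)
  set.seed(config$seed)
  n <- nrow(X)
  test_idx <- sample.int(n, max(1L, floor(test_fraction * n)))
  tr_idx <- setdiff(seq_len(n), test_idx)
  out <- lapply(rates, function(r) {
    cfg <- config
    cfg$dropout_rate <- r
    model <- train_mlp(X[tr_idx, , drop = FALSE], labels[tr_idx], cfg)
    pred <- predict(model, X[test_idx, , drop = FALSE])
    truth <- labels[test_idx]
    data.frame(rate = r, ari = ari(truth, pred), nmi = nmi(truth, pred),
               acc = accuracy(truth, pred))
  })
  do.call(rbind, out)
}
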