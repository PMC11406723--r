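#' Pipeline configuration
#'
#' One object drives every stage. A single master seed fans out
#' deterministically to the stage seeds (train/test split, network
#' training, cross-validation folds).
#'
#' @param resolution Bin width in bp.
#' @param min_contacts QC depth threshold.
#' @param impute An [imputation_params()].
#' @param embed An [embed_params()].
#' @param hidden_sizes,dropout_rate,epochs,batch_size,learning_rate
#'   Classifier hyperparameters (see [model_config()]).
#' @param holdout_fraction Fraction of cells held out for final evaluation.
#' @param transductive Fit the PCA embedding on all cells jointly (the
#'   protocol under which train and test cells share the embedding space);
#'   the default `FALSE` fits on training cells only and projects held-out
#'   cells, avoiding information leakage.
#' @param cv_folds Optional fold count for cross-validation on the training
#'   cells (`NULL` skips CV).
#' @param seed Master seed.
#' @return An object of class `pipeline_config` (a plain list, YAML
#'   round-trippable via [write_pipeline_config()]).
#' @export
pipeline_config <- function(resolution = 1e6, min_contacts = 5000,
                            impute = imputation_params(),
                            embed = embed_params(),
                            hidden_sizes = c(256L, 64L), dropout_rate = 0.5,
                            epochs = 100L, batch_size = 32L,
                            learning_rate = 1e-2,
                            holdout_fraction = 0.3, transductive = FALSE,
                            cv_folds = NULL, seed = 1L) {
  stopifnot(resolution > 0, min_contacts >= 0,
            inherits(impute, "imputation_params"),
            inherits(embed, "embed_params"),
            holdout_fraction > 0, holdout_fraction < 1)
  structure(list(resolution = resolution, min_contacts = min_contacts,
                 impute = impute, embed = embed,
                 hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 holdout_fraction = holdout_fraction,
                 transductive = isTRUE(transductive),
                 cv_folds = if (is.null(cv_folds)) NULL else as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` an equal `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$impute <- unclass(x$impute)
  x$embed <- unclass(x$embed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    resolution = x$resolution, min_contacts = x$min_contacts,
    impute = do.call(imputation_params, x$impute),
    embed = do.call(embed_params,
                    x$embed[setdiff(names(x$embed), "center")]),
    hidden_sizes = x$hidden_sizes, dropout_rate = x$dropout_rate,
    epochs = x$epochs, batch_size = x$batch_size,
    learning_rate = x$learning_rate,
    holdout_fraction = x$holdout_fraction, transductive = x$transductive,
    cv_folds = x$cv_folds, seed = x$seed
  )
}

# Deterministic fan-out of the master seed to stage seeds (kept < 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

#' Run the full classification pipeline
#'
#' Reads pairs and chromosome sizes, bins intra-chromosomal read pairs at
#' the configured resolution, applies cell QC, imputes each kept cell by
#' convolution + random walk with restart, embeds cells by two-stage PCA,
#' trains the feed-forward classifier on a seeded training split, and
#' evaluates accuracy, ARI, NMI and macro one-vs-rest AUC on the held-out
#' cells (plus optional k-fold cross-validation on the training cells).
#'
#' @param pairs_path Pairs TSV (see [read_pairs()]).
#' @param chrom_sizes_path Two-column chrom.sizes table.
#' @param labels_path Labels TSV with header columns `cell_id`, `type`.
#' @param config A [pipeline_config()].
#' @return A list: `metrics` (held-out evaluation from
#'   [evaluate_predictions()], with `cv_mean_acc`/`cv_fold_acc` when CV is
#'   requested), `model`, `embedder`, `qc` (kept/removed counts and
#'   reasons), `splits` (train/test cell ids), `predictions` (data frame of
#'   held-out truth and prediction), `genome`, and `config`.
#' @export
run_pipeline <- function(pairs_path, chrom_sizes_path, labels_path,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  genome <- read_chrom_sizes(chrom_sizes_path, resolution = config$resolution)
  pairs <- read_pairs(pairs_path, genome)
  cells <- bin_pairs(pairs, genome)
  qc <- filter_cells(cells, min_contacts = config$min_contacts)
  kept <- qc$kept
  if (length(kept) < 10L) stop("too few cells pass QC")

  label_dt <- data.table::fread(labels_path, sep = "\t",
                                colClasses = list(character = 1:2))
  if (!all(c("cell_id", "type") %in% names(label_dt))) {
    data.table::setnames(label_dt, seq_len(2L), c("cell_id", "type"))
  }
  lab <- stats::setNames(label_dt$type, label_dt$cell_id)
  kept_ids <- vapply(kept, function(c) c$cell_id, character(1))
  have_label <- kept_ids %in% names(lab)
  kept <- kept[have_label]
  kept_ids <- kept_ids[have_label]
  y <- unname(lab[kept_ids])

  # stratified holdout: cell types are often heavily imbalanced, so the
  # evaluation split preserves per-type proportions
  set.seed(derive_seed(config$seed, 1L))
  n <- length(kept)
  test_idx <- sort(unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    take <- floor(config$holdout_fraction * length(idx))
    if (take >= 1L) sample(idx, take) else integer()
  })))
  if (length(test_idx) == 0L) test_idx <- sample.int(n, 1L)
  tr_idx <- setdiff(seq_len(n), test_idx)

  imputed <- impute_cells(kept, config$impute)
  embed_par <- config$embed
  # cap component counts at what the (training) cohort can support
  fit_ids <- if (config$transductive) kept_ids else kept_ids[tr_idx]
  m_fit <- length(fit_ids)
  embed_par$k_chrom <- min(embed_par$k_chrom, m_fit - 1L)
  embed_par$k_cell <- min(embed_par$k_cell,
                          embed_par$k_chrom * length(genome$chrom_names),
                          m_fit - 1L)
  embedder <- embed_cells(imputed[fit_ids], genome, embed_par)
  X_all <- if (config$transductive) {
    embedder$embedding
  } else {
    rbind(embedder$embedding, project_cells(embedder, imputed[kept_ids[test_idx]]))
  }
  X_all <- X_all[kept_ids, , drop = FALSE]

  mcfg <- model_config(
    input_dim = ncol(X_all), n_classes = length(unique(y)),
    hidden_sizes = config$hidden_sizes, dropout_rate = config$dropout_rate,
    epochs = config$epochs, batch_size = config$batch_size,
    learning_rate = config$learning_rate,
    seed = derive_seed(config$seed, 2L)
  )
  model <- train_mlp(X_all[tr_idx, , drop = FALSE], y[tr_idx], mcfg)

  pred <- predict(model, X_all[test_idx, , drop = FALSE])
  scores <- predict_proba(model, X_all[test_idx, , drop = FALSE])
  metrics <- evaluate_predictions(y[test_idx], pred, scores)

  if (!is.null(config$cv_folds)) {
    cv <- kfold_cv(X_all[tr_idx, , drop = FALSE], y[tr_idx],
                   k = config$cv_folds,
                   seed = derive_seed(config$seed, 3L), config = mcfg)
    metrics$cv_mean_acc <- cv$mean_acc
    metrics$cv_fold_acc <- cv$fold_acc
  }

  list(metrics = metrics, model = model, embedder = embedder,
       qc = list(n_input = length(cells), n_kept = length(qc$kept),
                 n_removed = length(qc$removed), reasons = qc$reasons),
       splits = list(train = kept_ids[tr_idx], test = kept_ids[test_idx]),
       predictions = data.frame(cell_id = kept_ids[test_idx],
                                truth = y[test_idx], predicted = pred,
                                stringsAsFactors = FALSE),
       genome = genome, config = config)
}
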