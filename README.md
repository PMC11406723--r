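# scHiCtype

Cell-type classification from single-cell Hi-C contact maps.

Single-cell Hi-C (scHi-C) measures pairwise chromatin contacts within
individual cells, but each cell yields only a few thousand read pairs —
contact matrices so sparse that distinguishing cell types from them is hard.
`scHiCtype` implements a complete supervised pipeline for this problem:

1. **Binning & QC** (`read_pairs()`, `bin_pairs()`, `filter_cells()`) —
   intra-chromosomal read pairs are binned at a fixed resolution (default
   1 Mbp) into one symmetric contact matrix *A* per chromosome per cell,
   with *n = ⌈L/R⌉* bins for a chromosome of length *L* at resolution *R*.
   Cells with fewer than 5,000 total contacts, or with any chromosome
   carrying no read pair, are removed.
2. **Imputation** (`impute_cells()`) — each matrix is densified by a 3×3
   mean-filter convolution followed by random walk with restart,
   *Q ← p·Q·P + (1−p)·I* with *p = 0.5* on the row-normalized contact graph,
   then optionally binarized to its top 20% of entries.
3. **Embedding** (`embed_cells()`) — two-stage PCA: the flattened
   upper-triangle features of every chromosome are reduced to 10 components
   per chromosome, concatenated in genome order, and reduced again to a
   20-dimensional per-cell embedding. Fitted transforms are stored so
   held-out cells are projected, never refit.
4. **Classification** (`train_mlp()`, `predict()`) — a feed-forward network
   with two ReLU hidden layers (256, 64), inverted dropout (rate 0.5), and a
   per-class sigmoid output trained with elementwise binary cross-entropy by
   seeded mini-batch gradient descent with momentum and early stopping.
5. **Evaluation** (`evaluate_predictions()`, `kfold_cv()`) — accuracy,
   adjusted Rand index (ARI), normalized mutual information
   (NMI = 2·MI/(H(A)+H(B)), natural log), one-vs-rest ROC/AUC (trapezoid
   rule), per-class TPR/FPR, and seeded 10-fold cross-validation.

A seeded synthetic scHi-C generator (`sim_params()`, `generate_dataset()`)
emulates the data regime the pipeline targets — genomic distance decay,
type-specific contact blocks, very sparse per-cell depth straddling the QC
threshold, optional type imbalance — so every stage can be exercised with no
external data.

## Worked example

Simulate a 4-type, 200-cell dataset with clear type structure, then run the
whole pipeline:

```r
library(scHiCtype)

p   <- sim_params(n_types = 4L, cells_per_type = rep(50L, 4),
                  block_strength = 3, seed = 0L)
d   <- generate_dataset(p, "demo_data")
cfg <- pipeline_config(seed = 0L, cv_folds = 10L)
res <- run_pipeline(d$pairs, d$sizes, d$labels_path, cfg)

cat(sprintf("QC: kept %d of %d cells\n", res$qc$n_kept, res$qc$n_input))
m <- res$metrics
cat(sprintf("held-out ACC %.3f  ARI %.3f  NMI %.3f  macro-AUC %.3f\n",
            m$acc, m$ari, m$nmi, m$auc))
cat(sprintf("10-fold CV mean accuracy %.3f\n", m$cv_mean_acc))
```

```
QC: kept 159 of 200 cells
held-out ACC 1.000  ARI 1.000  NMI 1.000  macro-AUC 1.000
10-fold CV mean accuracy 1.000
```

41 of the 200 simulated cells fall below the 5,000-contact threshold and are
removed by QC, matching the sparse regime of real combinatorial scHi-C
libraries. The remaining cells are embedded and classified; on this clearly
structured simulation the held-out predictions are perfect, and the trained
model itself prints as:

```r
res$model
#> schic_mlp: 20-256-64-4, dropout 0.50, loss sigmoid_bce, classes: type1, type2, type3, type4
#>   trained 100 epoch(s); final train loss 0.0117 acc 1.000
```

`res$predictions` holds the held-out truth/prediction table, and
`res$model$history` the per-epoch train/validation loss and accuracy curves.
With `block_strength = 1` the generator emits no type signal at all and the
same pipeline scores at chance — a useful negative control.

## Command line

A thin CLI over the same functions is installed with the package
(`exec/schictype`): `simulate`, `bin`, `qc`, `impute`, `embed`, `train`,
`predict`, `evaluate`, and `run` (the full pipeline). For example:

```sh
Rscript exec/schictype simulate --out demo --cells-per-type 50,50,50,50 \
    --block-strength 3 --seed 0
Rscript exec/schictype run --pairs demo/pairs.tsv \
    --chrom-sizes demo/chrom.sizes --labels demo/labels.tsv \
    --out demo_out --seed 0
```

Every command takes `--seed`; all randomness in the package derives from the
supplied seeds, so reruns are bit-identical.

## Documentation

The methods vignette (`vignettes/schic-cell-type-classification.Rmd`)
describes the model, its assumptions, all tunable parameters, what the
synthetic generator does and does not emulate, and the package's numerical
conventions.
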