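---
title: "Classifying cell types from single-cell Hi-C contact maps"
author: "scHiCtype authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cell types from single-cell Hi-C contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scHiCtype)
```

## The problem

Single-cell Hi-C assays capture pairwise chromatin contacts inside
individual cells. A typical combinatorial scHi-C cell carries on the order
of 5,000–50,000 usable read pairs — spread over an entire genome, this makes
each per-chromosome contact matrix extremely sparse. Yet chromatin
architecture differs between cell types at the compartment scale, so a
sufficiently denoised, low-dimensional representation of each cell's contact
maps carries enough signal for supervised cell-type prediction. `scHiCtype`
implements that idea end to end: binning and quality control, imputation,
two-stage PCA embedding, a small feed-forward classifier, and the evaluation
metrics used to judge it.

This vignette explains the model behind each stage, the parameters that
matter, the numerical conventions, and what the bundled synthetic data
generator does and does not establish about real data.

## Binning and quality control

Read pairs are consumed from a minimal tab-delimited dialect (`cell_id`,
`chrom_a`, `pos_a`, `chrom_b`, `pos_b`, optional `count`), with 1-based
positions. Only intra-chromosomal pairs are used: at megabase resolution the
informative structure is within-chromosome, and inter-chromosomal contacts
in scHi-C are dominated by noise and artifacts. Each chromosome of length
$L$ is segmented into non-overlapping bins of width $R$ (default
$R = 10^6$ bp). We use $n = \lceil L/R \rceil$ bins — the ceiling, rather
than truncation, so that positions in the chromosome tail still have a bin —
and assign position $p$ to 0-based bin $\lfloor (p-1)/R \rfloor$. Counts
accumulate symmetrically into the $n \times n$ matrix $A$ (off-diagonal
entries mirrored, diagonal counted once), and symmetry of $A$ is exact
because the counts are integers.

Quality control removes cells that cannot support an embedding:

* **depth** — a cell's total contact count (the upper triangle of each $A$
  including the diagonal, summed over chromosomes, so each read pair counts
  once) must be at least `min_contacts` (default 5,000; a cell with exactly
  5,000 passes);
* **coverage** — a cell with even one chromosome carrying no read pair is
  excluded, because its flattened feature block would be identically zero
  and meaningless.

`filter_cells()` reports machine-readable reason codes (`LOW_DEPTH`,
`EMPTY_CHROM`) for every removed cell. Whether the depth threshold is
applied to raw or binned contacts is immaterial here because binning
preserves intra-chromosomal mass; we count binned mass.

## Imputation: convolution + random walk with restart

Sparse single-cell matrices are densified in two steps, per chromosome.

**Mean-filter convolution.** Each entry is replaced by the mean of its
$(2\,\text{pad}+1)^2$ window (default pad 1, a 3×3 window). Borders are
zero-padded and the divisor is always the full window size; this attenuates
edge bins slightly but keeps the operator linear and symmetric, and avoids
special-casing window shapes. Genomically neighboring bin pairs share
contact propensity, so local averaging recovers signal the shallow
sequencing missed.

**Random walk with restart.** The smoothed matrix is row-normalized into a
transition matrix $P$ (rows with no mass become self-loops, avoiding a
division by zero), and we iterate

$$Q_{t+1} = p \, Q_t P + (1-p) I, \qquad Q_0 = I,$$

with restart weight $p = 0.5$, until the maximum row-wise $L_1$ change
falls below `tol` ($10^{-6}$) or `max_iter` (30) is reached. Because $P$ is
row-stochastic, every iterate is row-stochastic, and the iteration is a
contraction with rate $p$, so 30 iterations reach the $10^{-6}$ scale. The
fixed point $(1-p)(I - pP)^{-1}$ mixes multi-step contact paths into every
entry — bins in the same compartment light up jointly even if no direct
read pair connects them. Since $QP$ need not stay symmetric, the result is
symmetrized as $(Q + Q^\top)/2$. Row normalization makes the output
invariant to uniform scaling of the input, removing per-cell depth from the
features.

**Binarization.** By default the imputed matrix is reduced to its top 20%
of entries (set to 1, rest 0), a rank-based cleanup that discards the
diffuse low tail the random walk spreads everywhere and equalizes scale
across cells. Ties at the cutoff break deterministically by (row, column)
order, which can leave at most one off-diagonal pair asymmetric; the
embedding reads only the upper triangle, so this has no downstream effect.
Whether to binarize at all is a genuinely open choice — the pipeline is
well-behaved either way — so `imputation_params(binarize = FALSE)` is a
first-class setting, not a hack.

All imputation parameters live in `imputation_params()`; the defaults
(pad 1, restart 0.5, top 20%) follow the established convention for
smoothing-plus-diffusion preprocessing of scHi-C matrices. The whole module
is deterministic.

## Two-stage PCA embedding

For each chromosome, every cell's imputed matrix is flattened to its
$n(n+1)/2$ upper-triangle features (fixed row-wise order) and the cohort
matrix is reduced to `k_chrom` principal components (default 10). The
per-chromosome scores are concatenated in genome order and reduced again to
`k_cell` components (default 20) — the final embedding each cell carries
into the classifier. Splitting the PCA by chromosome keeps the first stage
tractable (features never mix across chromosomes, so each fit is small) and
lets every chromosome contribute equally before the second stage finds
cross-chromosome structure.

Numerical conventions: columns are always mean-centered (variance scaling is
off by default — binarized features are already on a common scale); each
component's sign is fixed by forcing its largest-magnitude loading positive,
which makes the whole pipeline bit-reproducible; components are computed by
exact singular value decomposition, so there is no randomized solver to
seed. `pca_embed()` stores center, scale and rotation, and
`project_cells()` pushes held-out cells through the stored transforms.

The component counts are design choices, not estimates: 10 per chromosome
captures compartment-scale variation at 1 Mbp with tens-to-hundreds of
cells, and 20 final dimensions is comfortably above the number of cell
types while small enough for a tiny network. Both are exposed in
`embed_params()`. When a training cohort is smaller than the requested
counts, `run_pipeline()` caps them at the feasible rank.

**Inductive by default.** The embedding can be fit on all cells jointly
(transductive) or on training cells only, projecting held-out cells through
the frozen transforms (inductive). Joint fitting leaks information from
evaluation cells into the representation, so the pipeline defaults to the
inductive protocol; `pipeline_config(transductive = TRUE)` reproduces the
joint variant for comparison.

## The classifier

A fully connected network maps the $M \times N$ embedding to per-type
scores: two hidden layers (defaults 256 and 64 units) with ReLU activations,
and an output layer with an elementwise sigmoid per class, trained against
one-hot targets with mean elementwise binary cross-entropy. The sigmoid
output treats each type one-vs-rest and behaves gracefully when type
frequencies are very unbalanced; a `softmax_ce` switch in `model_config()`
gives the coupled softmax/categorical-cross-entropy variant. Prediction is
the argmax of the scores either way, ties resolving to the earlier class in
the vocabulary.

Training is plain mini-batch gradient descent (batch 32) with classical
momentum 0.9. The default learning rate is 0.01: with the loss averaged
over all $M \times K$ output entries, gradient magnitudes scale inversely
with the class count, and a rate of 0.001 demonstrably underfits even a
linearly separable embedding within the default 100 epochs, while 0.01
converges cleanly across the regimes the tests cover. Inputs are z-scored
with statistics of the training cells (stored in the model, reapplied at
prediction) so the rate is meaningful regardless of embedding scale.

Regularization is **inverted dropout** on the hidden activations (default
rate 0.5): during training each hidden unit is dropped with probability
$r$ and the survivors are scaled by $1/(1-r)$, so the evaluation-mode
forward pass needs no rescaling and the average of many training-mode
passes approximates the deterministic pass. Held-out agreement scores
(ARI/NMI/ACC) on sparse scHi-C embeddings peak around $r = 0.5$ — a sweep
utility, `dropout_sweep()`, reproduces this diagnostic on any dataset. A
10% validation split drives early stopping: training stops after
`early_stop_patience` (10) epochs without a new validation-loss minimum and
the best-validation weights are restored. Every random element — weight
initialization (scaled-uniform, $U(\pm 1/\sqrt{\text{fan-in}})$), the
validation split, batch shuffling, dropout masks — derives from the single
`seed` in `model_config()`, so identical calls produce identical weights.
Gradients are analytic and are verified against central finite differences
in the test suite.

## Evaluation

All quantities are computed from first principles on a shared contingency
substrate:

* **NMI** $= 2\,\mathrm{MI}/(H(A)+H(B))$ with natural logarithms and the
  $0 \log 0 = 0$ convention; when both partitions are trivial (one class
  each) both entropies vanish and 1.0 is returned, since the partitions are
  then structurally identical.
* **ARI** is the permutation-model adjusted Rand index over pair counts;
  a degenerate denominator (agreement cannot exceed chance) returns 1.0.
* **ROC/AUC** sweeps all distinct score thresholds descending with ties
  collapsed; the trapezoid-rule area equals the tie-corrected Mann–Whitney
  statistic, which the tests assert to $10^{-10}$. Multiclass AUC is the
  macro average of one-vs-rest curves over the classes present.
* **TPR/FPR** follow $TP/(TP+FN)$ and $FP/(TN+FP)$, with empty
  denominators reported as 0 with a warning rather than NaN.
* **k-fold CV** uses seeded random folds whose sizes differ by at most one
  (default $K = 10$, unstratified, matching the plain random-division
  protocol; a stratified mode exists for imbalanced data), training on
  $K-1$ folds and averaging held-out accuracy.

`run_pipeline()` evaluates on a held-out fraction of cells (default 30%).
This split *is* stratified by type: the realistic regime for this method
has type frequencies as skewed as 45 : 746 : 1759 : 111, where an
unstratified split can leave a rare type essentially absent from
evaluation and makes the reported accuracy a lottery of the split rather
than a property of the model.

## The synthetic data generator

`generate_dataset()` produces labelled datasets with exactly the structure
the pipeline assumes, and nothing more:

* a per-chromosome baseline contact probability
  $B_{ij} \propto (1+|i-j|)^{-\alpha}$ (default $\alpha = 1$), the
  genomic distance decay of contact frequency;
* per type, a few (default 3 per chromosome) seeded contiguous diagonal
  blocks multiplied by `block_strength` — compartment-scale, type-specific
  contact enrichment. `block_strength = 1` gives identical maps for all
  types, a built-in negative control; the structured setting used in the
  end-to-end tests is `block_strength = 3`;
* per-cell depths from a negative binomial (mean 10,000, dispersion 0.3,
  variance $\mu + 0.3\mu^2$), deliberately straddling the 5,000-contact QC
  threshold so the filter has non-trivial behavior; cell contacts drawn
  multinomially from the type's map, so a cell's total equals its depth
  exactly;
* serialization in the exact pairs/chrom.sizes/labels formats the pipeline
  reads, byte-identical under a fixed seed.

The default genome is two 50-bin (50 Mbp) toy chromosomes; the default
cohort is 4 types × 50 cells, small enough that the entire pipeline runs in
seconds but large enough for a meaningful train/test split after QC.

What the generator does **not** emulate: TADs and loops below compartment
scale, cell-cycle variation, inter-chromosomal contacts, barcode collisions
or other library artifacts, and realistic karyotype differences between
lines. Passing the end-to-end tests therefore shows that the implementation
recovers planted compartment-scale type structure from realistically sparse
data — it does not certify accuracy levels on any real dataset, where
scores must be re-established empirically.

## Degenerate inputs and edge conventions

* Empty pairs files parse to an empty record stream; malformed or
  out-of-range records are skipped with line-numbered warnings or abort,
  per the configured policy.
* All-zero rows in the random-walk normalization become self-loops.
* Zero-variance features are left unscaled by standardization; identical
  rows yield an all-zero PCA block rather than an error.
* `epochs = 0` returns the untouched initialized network with empty
  history, useful for testing; a non-finite training loss aborts with a
  diagnostic pointing at the learning rate.
* Cell order is never silently changed: concatenating embeddings with
  mismatched row order is an error.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on generated data:
200-cell cohorts on the two-chromosome toy genome for end-to-end label
recovery and its negative control, 500 random partition pairs (n = 100, up
to 6 classes) for the metric oracles, 200 random score sets for the
AUC/Mann–Whitney identity, a 4×4 two-block matrix against 1,000 power
iterations for the random-walk fixed point, and a 5-cell batch for the
finite-difference gradient check. These sizes were chosen so the full suite
exercises every contract in well under the time a coffee takes, while the
statistical checks retain enough resolution to catch real defects.

## Known limitations

* The pipeline assumes a shared genome across cells; mixed-genome inputs
  must be harmonized upstream.
* Imputation parameters are global, not distance-stratified; no
  ICE/balancing normalization is applied (out of scope by design).
* The classifier is a deliberately small dense network; it is not intended
  to scale to thousands of input dimensions without adjusting
  `embed_params()` and `hidden_sizes`.
* Real scHi-C libraries carry artifacts (duplicate pairs, barcode
  collisions) that must be handled before the pairs file reaches this
  package.
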