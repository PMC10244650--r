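---
title: "Integrating paired single-cell omics with a modular autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating paired single-cell omics with a modular autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umint)
```

## The problem

Assays such as CITE-seq measure several molecular layers — mRNA expression
plus a panel of antibody-derived tags (ADTs), or mRNA plus chromatin
accessibility — in the *same* cells. The layers differ wildly in width
(thousands of genes against tens of proteins), in noise character
(zero-inflated counts against dense panels), and in scale, yet they reflect a
common underlying cell state. The integration task is to learn one
low-dimensional per-cell embedding that uses all layers, so that downstream
clustering, annotation and visualization see the joint signal rather than any
single modality.

A plain autoencoder can do this by stacking the modalities into one wide
matrix, but its dense input layer then spends most of its capacity — and its
parameters — on the widest modality. This package implements a *modular*
autoencoder: each modality gets its own encoding module, the modules are
fused at a shared bottleneck, and a mirrored decoder reconstructs every
modality from the bottleneck alone.

## The model

For modalities $X_1, \dots, X_m$ with $d_1, \dots, d_m$ features over the
same $n$ cells, the encoder computes, per modality $i$,

$$h_{2i} = \mathrm{ReLU}(W_{1i} x_i + b_{1i}), \qquad
  h_3 = \mathrm{ReLU}\Big(\sum_{i=1}^{m} W_{2i}\, h_{2i} + b_2\Big),$$

where $W_{1i}$ is $d_i \times n_i$ ($n_i$ the module width) and $h_3$, the
bottleneck activation of width $k$, is the embedding. The decoder mirrors
this: $h_{4i} = \mathrm{ReLU}(W_{3i} h_3 + b_{3i})$ and a *linear*
reconstruction $\tilde{x}_i = W_{4i} h_{4i} + b_{4i}$ (linear because the
preprocessed inputs are real-valued and roughly centered; a final
nonlinearity would bias the reconstructions).

Because modality $i$'s input connects only to its own module, the first
layer has $\sum_i d_i n_i$ weights instead of the dense
$(\sum_i d_i)(\sum_i n_i)$. The per-side saving is
$\sum_i d_i \sum_{j \ne i} n_j$ and the mirrored decoder saves the same
again — `parameter_reduction()` returns these closed forms, and
`model_weight_counts()` confirms a built model carries exactly those
entries. With one modality the saving is zero and the architecture *is* an
ordinary autoencoder, which is also how the package builds its baselines.

### Objective

Training minimizes

$$L = \frac{1}{n}\sum_{i=1}^m \lambda_i \lVert X_i - \tilde{X}_i \rVert_F^2
      + \alpha \sum_{j=2}^{4} \lVert h_j \rVert_1
      + \beta \sum_{j=2}^{4} \lVert W_j \rVert_F^2 ,$$

with Adam (learning rate 0.001, the optimizer's conventional default) for 25
epochs at batch size 16, and $\alpha = 10^{-4}$, $\beta = 10^{-3}$ by
default. Three choices here were genuinely open and are worth recording:

* **$\lambda_i$ defaults to $1/d_i$** (`lambdas = "auto"`). The balancing
  weights exist so a 2,000-gene modality cannot drown a 20-protein panel;
  $1/d_i$ makes every term a per-feature mean squared error, which achieves
  that balance exactly and is invariant to duplicating features (a property
  the test suite checks). Any positive vector can be supplied instead.
* **Regularization scope is read literally**: the index $j$ runs over the
  fusion, decoding and reconstruction layers, so the input-layer weights
  $W_{1i}$ carry no L2 penalty and the raw inputs no L1 penalty. If that
  exclusion is unwanted, `penalize_input_weights = TRUE` extends the L2 term
  to $j = 1$.
* **The activity penalty is averaged per cell** (the $1/n$ is applied to the
  L1 term batch-wise), so the meaning of $\alpha$ does not depend on batch
  size.

Module widths $n_i$ default to $\min(128, \max(16, \lceil d_i/8 \rceil))$ —
wide enough to not bottleneck a small panel, capped so a very wide modality
does not explode the model. Weights use seeded uniform Glorot
initialization; biases start at zero. Gradients are computed by hand-derived
backpropagation (the architecture is fixed, so autodiff machinery is
unnecessary); the test suite validates every layer's gradient against
central finite differences at points jittered off the ReLU kinks, where the
objective is differentiable.

### Determinism

A fixed `seed` controls initialization, per-epoch shuffling (each epoch
draws its own seed from the config seed) and any corruption noise, so one
configuration reproduces its loss trace and parameters exactly on the same
platform; across platforms agreement is only up to floating-point library
differences.

## Preprocessing

The `"rna"` recipe is the standard log-normalization chain: library-size
scaling so each cell sums to 10,000, `log1p`, selection of highly variable
features, then per-feature z-scoring (population variance) clipped to
$\pm 10$. Variable features are ranked by plain variance of the
log-normalized values — deterministic and dependency-free, rather than a
reimplementation of variance-stabilizing fits from other toolkits; the cut
defaults to 2,000 features and ties break by original feature order. The
`"adt"` recipe applies the centered log-ratio transform per cell (ADT panels
are per-cell compositions), with pseudocount 1 by default so zeros are legal;
with pseudocount 0 the classical CLR applies and each transformed cell sums
to exactly zero. Zero-variance features scale to all-zeros rather than NaN.
Cells are aligned across modalities on the *sorted* intersection of
barcodes, giving one canonical order independent of file order; dropped
counts are reported. Internally everything is cells × features; on-disk
orientation is handled only at the reader boundary.

Low-abundance ADT filtering is deliberately left to the caller: there is no
principled universal threshold, and silently dropping features would be
worse than documenting the decision.

## Evaluation

External indices are computed from the label contingency table: the adjusted
Rand index and the Fowlkes–Mallows index
($TP/\sqrt{(TP+FP)(TP+FN)}$ over unordered cell pairs). Both are verified in
the tests against a brute-force oracle that enumerates all pairs. When the
ARI denominator vanishes (both partitions trivial) the package returns 1 for
identical partitions and 0 otherwise — the standard convention. FMI returns
0 when either partition is all singletons.

Embeddings are clustered with seeded k-means (k-means++ initialization, best
of 10 restarts by within-cluster sum of squares) and with agglomerative
hierarchical clustering under Ward linkage (`ward.D2` on Euclidean
distances) — Ward because it is the conventional choice when a flat k-cut is
the goal; the linkage is a parameter. When labels are supplied, `k` defaults
to the number of distinct labels.

Reconstruction fidelity is scored geometrically: `reconstruction_rho()` is
the Pearson correlation between the condensed Euclidean pairwise-distance
vectors of a modality and its reconstruction (computed on a seeded subsample
of at most 1,000 cells to bound the $O(n^2)$ distance work), and the overall
reconstruction score `ors()` is the unweighted mean over modalities.
Euclidean distance matches the scaled, roughly Gaussian preprocessed data; a
reconstruction that is a global rescaling of the original scores 1 by
design. Internal indices are the mean silhouette width and the
Davies–Bouldin index (cluster scatter = mean distance to centroid); two
clusters sharing a centroid return an infinite DB rather than an error.

## The synthetic benchmark

`simulate_multiomics()` draws cluster centers in a shared latent space
(random directions, rescaled until all pairwise distances reach
`cluster_separation`), gives each cell a latent state $z = \text{center} +
N(0, I)$, and observes each modality through its own random loading matrix
with a softplus link: $\text{rate} = \mathrm{softplus}(zA_i)$. Count-like
modalities draw Poisson counts from the rate; Bernoulli dropout zero-masks
entries afterwards; optional per-batch feature shifts are added to the rate
(before the Poisson draw, so counts stay valid non-negative integers).

Defaults are the package's benchmark conditions: 2,000 cells, 5 equal
clusters, a 10-dimensional latent space with separation 6 (clearly separated
cell types with overlapping-scale within-cluster spread, the regime in which
annotated cell types usually live), modalities of 500 and 20 features, rate
noise 0.1, and 50% dropout in the wide modality only. These mirror the
structure of CITE-seq data at desk scale.

What the generator deliberately does **not** emulate: realistic library-size
variation across cells, gene–gene correlation beyond the shared latent
factors, negative-binomial overdispersion (the additive rate noise supplies
mild overdispersion instead), and fragment-level chromatin structure.
Passing the benchmark therefore demonstrates that the implementation
recovers planted joint structure under zero inflation and width imbalance —
not that it matches any particular published score on real tissue.

## Baselines

`train_baseline()` provides matched dense autoencoders: plain (AE),
denoising (DAE: inputs corrupted during training only, by additive Gaussian
noise scaled per feature's standard deviation or by random masking, with the
loss against clean targets) and sparse (SAE: L1 on hidden activations). All
three are built as the one-modality special case of the modular network, so
"identical hyperparameters" is enforced by construction, and setting the
DAE's noise or the SAE's sparsity to zero reproduces the AE's loss trace
bit for bit. `run_compare()` repeats training over fresh 80:20 train/test
splits, scoring reconstruction (ORS) on held-out cells and clustering on all
cells — the split protocol is fixed here because reconstruction scored on
training cells would flatter whichever model memorizes best.

## Problem sizes and runtime

The shipped tests train on 2,000-cell benchmarks (about 10 s per 25-epoch
run on one CPU core) and on 60–120-cell miniatures for contract checks; the
acceptance workflow in `scripts/acceptance.R` runs one full benchmark in
under a minute. These sizes were chosen so the full suite exercises every
code path, including ten independent benchmark trainings, in a few minutes.

## Known limitations

One encoding and one decoding layer per modality (deeper stacks are out of
scope for this version); cells must be paired across modalities (no mosaic
integration or missing-modality imputation); batch effects are absorbed only
as far as the shared bottleneck happens to discard them — there is no
explicit correction term; and feature-level importance extraction from the
modules is not implemented.
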