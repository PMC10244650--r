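# umint

Unsupervised integration of paired single-cell multi-omics data with a
modular neural network.

## What problem this solves

Multi-modal single-cell assays (CITE-seq, 10x multiome) measure several
molecular layers — thousands of genes next to tens of surface proteins, or
chromatin peaks — in the same cells. Analysts need one per-cell embedding
that combines all layers for clustering and annotation. Stacking the
modalities into a dense autoencoder works, but the dense input layer is
dominated by the widest modality and carries far more parameters than
needed.

This package implements a modular autoencoder for that task. Each modality
`X_i` (cells × `d_i`) has its own encoding module of width `n_i`,

```
h_2i = ReLU(W_1i x_i + b_1i)
h_3  = ReLU(Σ_i W_2i h_2i + b_2)        # the k-dimensional embedding
```

and a mirrored decoder (`h_4i = ReLU(W_3i h_3 + b_3i)`, linear readout
`x̃_i = W_4i h_4i + b_4i`) reconstructs every modality from the shared
bottleneck. The first layer has `Σ d_i n_i` weights instead of the dense
`(Σ d_i)(Σ n_i)`; the per-side saving `Σ_i d_i Σ_{j≠i} n_j` doubles across
encoder and decoder. Training minimizes

```
L = (1/n) Σ_i λ_i ‖X_i − X̃_i‖² + α Σ_{j=2..4} ‖h_j‖₁ + β Σ_{j=2..4} ‖W_j‖²
```

with Adam (25 epochs, batch 16, α = 1e-4, β = 1e-3 by default) and
λ_i = 1/d_i so that no modality drowns the others. Backpropagation, Adam
and the architecture are implemented in plain R matrix algebra.

Also included: matched dense autoencoder baselines (AE / denoising /
sparse), the closed-form parameter accounting, standard preprocessing
(library-size + log normalization, highly variable features, centered
log-ratio for antibody panels, scaling), clustering metrics (ARI,
Fowlkes–Mallows, silhouette, Davies–Bouldin), a distance-correlation
reconstruction score, and a seeded synthetic paired-omics generator so the
whole pipeline is testable without downloads.

## Worked example

```r
library(umint)

# simulate a CITE-seq-like benchmark: 2,000 cells, 5 cell types,
# a 500-feature count modality with 50% dropout + a 20-feature panel
sim <- simulate_multiomics(simulation_config(seed = 1))

# standard per-modality preprocessing
data <- paired_dataset(list(
  preprocess_modality(sim$data$modalities[[1]], "rna", n_hvg = 500),
  preprocess_modality(sim$data$modalities[[2]], "adt")),
  labels = sim$true_labels)

# train with the default protocol and embed
fit <- train_umint(data, umint_config(seed = 1))
fit
#> umint_model: 2 modalities, dims (500,20), hidden (63,16), bottleneck 64
#> first-layer weights: 31820 (dense equivalent 41080)
#> trained 25 epochs: loss 1.8725 -> 0.921351

embedding <- umint_encode(fit$model, data)
run_evaluate(embedding, labels = setNames(data$labels, embedding$cell_ids))
#> kmeans       k=5  ARI 1.0000  FMI 1.0000  silhouette 0.6219  DB 0.6079
#> hierarchical k=5  ARI 1.0000  FMI 1.0000  silhouette 0.6219  DB 0.6079

parameter_reduction(c(500, 20), fit$model$config$hidden_widths)
#> first-layer weights: modular 31820 vs dense 41080 (reduction 9260 per side, 18520 total)
```

The training loss falls from 1.87 to 0.92 over 25 epochs; k-means and Ward
clustering of the 64-dimensional embedding both recover the five simulated
cell types exactly (ARI = FMI = 1), and the modular first layer carries
9,260 fewer weights than the matched dense autoencoder (18,520 across the
mirrored pair). `run_compare()` repeats this head-to-head against the AE,
DAE and SAE baselines over fresh 80:20 splits, and
`inst/cli/umint.R` exposes `simulate` / `train` / `evaluate` / `compare`
subcommands for shell use.

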