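# duogate

Joint embedding of paired transcriptome and proteome profiles — CITE-seq
style RNA + ADT measurements of the same cells, with or without spatial
coordinates — using a dual-path graph-attention auto-encoder.

Droplet assays now routinely measure two molecular layers per cell: a
sparse, high-dimensional RNA count vector and a dense, low-dimensional
antibody-derived-tag (ADT) panel.  `duogate` integrates the two into a
single low-dimensional representation per cell, for clustering and any
downstream analysis that wants both layers at once.  It is aimed at
analysts working with paired single-cell or spatially resolved
multi-omics data at the scale of hundreds to a few thousand cells.

## Method

For each modality a directed k-nearest-neighbour graph is built — from
PCA-reduced RNA profiles and CLR-normalised protein profiles in
single-cell mode, or from tissue coordinates in spatial mode — and edges
whose endpoints fall in different Leiden communities are pruned:

    TN'_i = { c_j in TN_i : tl(c_j) = tl(c_i) },    W = D ∘ B,

with `B[i,j] = 1` iff cell j survives in cell i's pruned neighbour set and
D the pairwise distance matrix.  Each modality then passes through its own
graph-attention auto-encoder: a two-layer encoder (single-head additive
attention in the first layer only; ReLU then Tanh) and a mirrored decoder.
The per-path embeddings are concatenated into the joint representation

    Z = [ T_emb | P_emb ],

and training minimises the combined weighted loss

    L = (L_recon^t + L_recon^p) + λ (L_super^t + L_super^p),

where the reconstruction terms are per-modality MSE and the
self-supervision terms are triplet losses on Z, with positives drawn from
each cell's pruned neighbours and negatives from other communities.
Defaults follow the method's standard operating point: 15 neighbours,
30-dimensional per-path embedding (Z has 60 columns), 300 epochs,
λ = 0.1, learning rate 0.001.

The package also ships the matching evaluation protocol (Purity,
Homogeneity, ARI, NMI over a Leiden resolution sweep 0.1–1.0; Robust Rank
Aggregation p-values; graded Gaussian-noise robustness) and a seeded
generator of paired counts with planted cluster structure, optionally laid
out as contiguous spatial regions.

## A worked example

```r
library(duogate)

sim <- simulate_multiomics(seed = 1)   # 600 cells, 3 clusters, 200 genes, 30 ADTs
sim
#> duogate_sim: 600 cells, 3 clusters, 200 genes, 30 proteins
#> RNA zero-fraction 0.45, protein zero-fraction 0.00

fit <- duogate(sim$rna, sim$protein, seed = 1)
fit
#> Dual-path graph-attention auto-encoder integration
#>   mode: single_cell | cells: 600 | RNA features: 200 | proteins: 30
#>   joint embedding: 600 x 60 (per path 30)
#>   300 epochs, final loss 2.54834 (recon 2.51798 + 0.02164, super 0.07459 + 0.01261, lambda 0.1)

report <- sweep_and_report(fit$Z, sim$labels, seed = 1)
max(report$ari)
#> [1] 0.9268329
```

The printed fit shows the loss split into its four components; the sweep
report scores the embedding's Leiden clusterings against the generator's
planted labels at ten resolutions, and the best ARI over the sweep
(0.93 here) says the planted cell populations are recovered nearly
perfectly from the joint embedding.  `predict(fit, type = "clusters")`,
`plot(fit)`, `residuals(fit)` and `write_duogate(fit, dir)` expose the
usual model-object surface.

Spatial data work the same way — pass `coords` and the neighbour graphs
are built from tissue positions instead of expression:

```r
sp <- simulate_multiomics(grid = c(30, 20), seed = 1)
fit_sp <- duogate(sp$rna, sp$protein, coords = sp$coords, seed = 1)
```

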