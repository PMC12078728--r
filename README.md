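# toxicoclust

Robust hierarchical co-clustering of toxicogenomic fold-change matrices.

## What it does

Toxicology screens summarise expression as a fold-change gene-expression
(FCGE) matrix `F`: genes in rows, doses-of-chemicals (DCs) in columns, each
cell the replicate-mean log2 ratio of treated over control expression. The
scientific target is the *co-cluster* — the block at the intersection of
one gene cluster (GC) and one DC cluster (DCC) — because a DC group with a
shared mechanism up-regulates one gene group and down-regulates another.
Genes in significant blocks are toxicogenomic biomarkers; the DCs in the
same blocks are their chemical regulators.

The pipeline:

1. **Robust transform** — map every fold change through the bounded
   logistic `L(F) = 1 / (1 + exp(-F))`, so `L(0) = 0.5` and all values lie
   in (0, 1). Outlying fold changes saturate instead of dominating the
   distances; `robust = FALSE` gives the classical pipeline on raw `F`.
2. **Two-way hierarchical clustering** — genes and DCs separately, with
   euclidean/manhattan/Minkowski distances and `ward.D` / `ward.D2`
   linkages (default euclidean + `ward.D2`), cut into `k_genes` and
   `k_dcs` clusters.
3. **Co-cluster grid** — per block, the mean transformed value (aLFCGE);
   clusters relabelled so the largest block means run down the principal
   diagonal.
4. **Control-chart calls** — a Shewhart-style subgroup-means chart on the
   transformed values (subgroups = blocks, limits `CL ± k·σ/√n̄`): blocks
   above the UCL are significant up-regulatory biomarker co-clusters,
   blocks below the LCL down-regulatory.

A block-model simulator with ground truth, casewise (Tukey–Huber) and
cellwise (independent) contamination, clustering error rate with optimal
label matching, and Tukey sensitivity curves support the robustness
analysis end-to-end; bipartite gene–chemical networks are exported as edge
lists or GraphML.

## Worked example

```r
library(toxicoclust)

sim <- simulate_fcge(seed = 1)       # benchmark design: 50 x 36, blocks +/-3, noise var 0.35
fit <- hcoclust(sim$fcge, k_genes = 4, k_dcs = 3)
summary(fit)
```

```
Hierarchical co-clustering (robust mode)
  50 genes in 4 clusters, 36 DCs in 3 clusters (euclidean + ward.D2)
  12 co-clusters: 2 up-regulatory, 2 down-regulatory, 8 insignificant
Control limits (xbar_pooled, k = 3): LCL 0.465436 | CL 0.496191 | UCL 0.526946

Ranked co-clusters:
 gc dcc    aLFCGE n_cells rank  significance
  1   1 0.9479030     100    1            up
  2   2 0.9413780     100    2            up
  3   3 0.5026410     320    3 insignificant
  4   3 0.5004730     160    4 insignificant
  3   2 0.5000060     200    5 insignificant
  4   1 0.4998660     100    6 insignificant
  1   3 0.4928270     160    7 insignificant
  3   1 0.4911430     200    8 insignificant
  2   3 0.4831550     160    9 insignificant
  1   2 0.4750420     100   10 insignificant
  2   1 0.0583205     100   11          down
  4   2 0.0558537     100   12          down
```

Reading the output: the twelve blocks are the 4 x 3 co-cluster grid. The
two blocks with aLFCGE ≈ 0.94 sit above the UCL — gene clusters 1 and 2 are
up-regulated biomarker clusters, driven by DC clusters 1 and 2
respectively. The two blocks near 0.06 fall below the LCL (down-regulatory)
and the eight blocks near 0.5 are unregulated background. Both recovered
partitions match the generator's truth exactly:

```r
error_rate(fit$gene_clusters, sim$gene_clusters)$er   # 0
error_rate(fit$dc_clusters,  sim$dc_clusters)$er      # 0
```

`plot(fit)` draws the block-reordered heatmap, `plot(fit, "chart")` the
control chart, `coef(fit)` returns the 4 x 3 block-mean matrix, and
`cocluster_graph(fit)` / `member_graph(fit)` build the regulatory networks.
`run_pipeline(outdir = "...")` writes the full TSV/JSON results bundle, and
`inst/scripts/toxicoclust` wraps simulate/cocluster/evaluate/sweep/network
as shell subcommands.

The robustness case for the transform, in two lines: under casewise
contamination of 20% of rows with N(±10, 1) outliers, the classical
pipeline's gene-clustering error rate averages ~60%, the robust pipeline's
~20% (the contaminated rows themselves); see `contamination_sweep()`.

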