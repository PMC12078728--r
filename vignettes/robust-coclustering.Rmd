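---
title: "Robust hierarchical co-clustering of toxicogenomic fold-change matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust hierarchical co-clustering of toxicogenomic fold-change matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxicoclust)
```

## The problem

A toxicogenomic screen exposes animals to doses of chemicals (DCs) and
profiles gene expression in treated and control groups. The working data
structure is the fold-change gene-expression (FCGE) matrix: rows are genes,
columns are DCs (one column per chemical x dose level x time point), and
each cell is the mean over replicates of the log2 ratio of treated over
control expression. Three questions are asked of such a matrix at once:
which genes are differentially expressed (the toxicogenomic biomarkers),
which DCs act through a shared mechanism, and which *pairs* of gene groups
and DC groups go together — a DC cluster that up-regulates one gene cluster
and down-regulates another. The co-cluster, the sub-matrix block at the
intersection of one gene cluster and one DC cluster, is the natural unit of
that third question.

Gene-expression pipelines also leak outliers: single wild fold changes from
hybridisation or normalisation artefacts, or whole corrupted arrays.
Ordinary hierarchical clustering is driven by distances, and a single
coordinate at fold change 20 contributes more to a Euclidean distance than
an entire block of genuine +/-3 signal, so one bad cell can re-wire the
dendrogram. The method implemented here makes the two-way clustering robust
with one cheap preprocessing step and adds a decision rule for which
co-clusters matter.

## The procedure

`hcoclust()` fits the model in four steps.

**1. Bounded transform.** Every fold change F is mapped through the
logistic function L(F) = 1 / (1 + exp(-F)). L(0) = 0.5, up-regulation lands
in (0.5, 1), down-regulation in (0, 0.5), and — the point of the exercise —
the output is bounded: an outlier at F = 100 and one at F = 10 both
transform to essentially 1, so their leverage on any distance is capped.
The transform is strictly monotone, so it never re-orders genuine effects.
`robust = FALSE` skips this step and gives the classical pipeline on raw
fold changes; everything downstream is otherwise identical, which makes the
robust/classical comparison exact.

**2. Two-way hierarchical clustering.** Genes and DCs are clustered
separately with agglomerative hierarchical clustering on profile distances
(`stats::dist` + `stats::hclust`). The supported combinations are
euclidean, manhattan and Minkowski distances crossed with the `ward.D` and
`ward.D2` linkage variants (plus single/complete/average for general use).
The default is euclidean + `ward.D2`, the variant whose Lance–Williams
recurrence acts on squared dissimilarities — the Ward formulation with the
cleanest variance interpretation. The Minkowski order defaults to p = 2.
The number of clusters is the analyst's choice from the dendrograms, as is
conventional for this method; `suggest_k()` automates the obvious
heuristic (largest merge-height gap, ties toward smaller k) but is advisory
only. The test suite cross-checks the agglomeration against an independent
brute-force Lance–Williams implementation that rescans the full
cluster-distance matrix at every step.

**3. Co-cluster grid and diagonal ranking.** Each (gene cluster, DC
cluster) pair is a co-cluster; its summary statistic is the aLFCGE, the
arithmetic mean of the transformed values in the block. Weighted by block
size, these means reconstitute the grand mean exactly — a conservation
identity the tests assert to 1e-9. Clusters are then relabelled so the
strongest up-regulatory blocks run down the principal diagonal: greedily
pick the largest block mean among pairs whose row and column cluster are
both still unlabelled, assign both the next index, and repeat; when the
shorter axis is exhausted the remaining clusters on the longer axis are
appended in descending order of their best block mean. The
descending-diagonal layout does not by itself determine an algorithm, so
the greedy rule is this package's construction; it is
deterministic (ties break toward the smallest original cluster id) and
idempotent. Because the relabelling depends on sampled block means, only
the multiset of block means and significance calls is reproducible across
reruns, not particular label strings.

**4. Control-chart significance.** Which blocks are far enough from the
bulk to call regulatory? The decision is a Shewhart-style control chart on
the transformed scale. Two sigma estimators are provided because both are
defensible charts for this geometry:

* `individuals` — CL = mean, limits CL ± k·sd over all values. Appropriate
  for cell-level regulation calls on the fold-change scale
  (`classify_cells()`, boundary-inclusive: a cell at exactly the UCL is
  called up).
* `xbar_pooled` (default for block calls) — a subgroup-means chart with the
  co-cluster blocks as subgroups: CL is the grand mean, sigma the pooled
  within-block standard deviation, limits CL ± k·sigma/sqrt(n̄) with n̄ the
  mean block size. A block is up-regulatory iff its mean strictly exceeds
  the UCL, down-regulatory iff strictly below the LCL.

The means-chart default is forced by the geometry of the problem: on the
benchmark simulation the signal blocks sit near 0.95/0.05 and baseline
blocks near 0.50, and only a chart whose sigma comes from *within-block*
spread scaled by block size separates them; a chart on the spread of the
twelve block means themselves would not. `k_sigma` defaults to the
conventional 3. The asymmetric boundary conventions (inclusive for cells,
strict for blocks) are deliberate and matter only on measure-zero ties.

One known sharpness limit: with limits at CL ± 3·sigma/sqrt(n̄), blocks
substantially *smaller* than n̄ have means with standard error larger than
sigma/sqrt(n̄), so an occasional small baseline block drifts past a limit.
On the benchmark design (smallest blocks 100 cells, n̄ = 150) this produces
a false significant block in roughly 5% of simulated datasets — the
observed per-dataset rate of a clean 2-up/2-down call is about 0.95.
Per-block limits using each block's own size would sharpen this, but the
single-limit chart is kept as the default for its simplicity and its
single pair of reportable limits.

## The simulator

`simulate_fcge()` is first-class, tested code, not a fixture. Its defaults
encode the benchmark study conditions: 50 genes in clusters of 10/10/10/20;
36 DCs in clusters of 10/10/16 (12 chemicals at Low/Middle/High labels,
grouped as C1–C5 High+Middle, C6–C10 High+Middle, and the remainder); block
means +3 (DCC1 up-regulates GC1, DCC2 up-regulates GC2), −3 (DCC1
down-regulates GC2, DCC2 down-regulates GC3) and 0 elsewhere; independent
Gaussian noise of **variance** 0.35 added to every cell. Ground-truth
partitions, the block regulation map and the contamination mask are
returned alongside the matrix. A replicate-level mode (`m = 3`) generates
per-replicate noise of the same variance and returns the replicate mean,
for the cell-level chart entry point.

What it emulates: block-structured signal at a realistic +/-3 log2
magnitude, homoscedastic noise, unequal cluster sizes, a signal-free DC
cluster. What it does not: correlation between genes within a pathway,
dose–response monotonicity across the Low/Middle/High columns of one
chemical, heteroscedastic or heavy-tailed measurement noise, and batch
structure. Passing tests on this generator therefore demonstrate recovery
of well-separated block structure under contamination, not performance on
the correlated, unbalanced matrices of a real screen.

Two contamination models cover the two standard corruption geometries of
the robust-statistics literature, the casewise/cellwise pair:

* `contaminate_thcm()` — casewise: each gene row is independently replaced
  in full with probability ε (a corrupted sample/probe);
* `contaminate_icm()` — cellwise: each cell independently with probability
  ε (scattered single-cell artefacts). At cell rate 0.025 and 36 columns,
  the probability a row is touched is 1 − 0.975^36 ≈ 0.598
  (`icm_casewise_rate()`), which is what makes small cellwise rates
  comparable to large casewise ones.

The contaminating distribution is N(±10, 1) with the sign drawn per
replacement — far outside the ±3 signal, so contamination is unambiguous —
and is fully configurable.

## Robustness diagnostics

`error_rate()` scores a predicted partition against the truth after
matching predicted to true clusters one-to-one to maximise overlap
(exhaustive optimal assignment up to 8 clusters a side, which covers any
realistic use; the matching makes the score invariant to label
permutations, and surplus clusters on either side count wholly as errors).
`contamination_sweep()` runs the generate–contaminate–cluster–score loop
over rates, metric/linkage combinations and both modes, sharing each
contaminated matrix across combinations so the robust/classical comparison
is paired.

`sensitivity_curve()` probes the influence of a single contaminated
observation y* on the 1-norm profile distance between two genes:
SC_n(y*) = n[T(y_1, …, y_{n−1}, y*) − T(y_1, …, y_{n−1})], with the
contaminated coordinate appended to gene i's profile and compared against a
reference coordinate of gene k. No single pairing of the contaminated
coordinate is canonical, so the reference is exposed as a flag, defaulting
to the mean of gene k's analysis-scale profile. In
robust mode everything passes through the logistic transform first, which
bounds the curve by n·max(ref, 1 − ref) exactly; in classical mode the
curve is n·|y* − ref|, unbounded in the contaminant. The finite-sample
form above is what is reported; its n → ∞ limit (the influence function,
which differs by the constant −T(F)) is noted here only.

## Numerical choices

* The logistic transform uses the two-branch form (exp(x)/(1+exp(x)) for
  negative x) so ±1e6 inputs saturate cleanly at 0/1 instead of dividing
  by overflowed exponentials; L(x) + L(−x) = 1 holds to 1e−12.
* Cluster indices from `cut_clusters()` are renumbered by first appearance
  in input order, making partitions comparable across runs.
* Merge tie-breaks inside `stats::hclust` are inherited as-is; the oracle
  comparison uses continuous random data where ties have measure zero.
* Degenerate inputs fail fast with named offenders: nonpositive
  expression, NA fold changes, mismatched labels, subgroups of size 1, k
  outside 1..n.
* All exported tables print floats at 6 significant digits, which pins
  byte-level reproducibility of the pipeline bundle for a fixed seed.

## Problem sizes in the test suite

The suite exercises the full benchmark design (50 × 36) at 30–40 simulated
datasets per statistical check, 1000 random instances of n ≤ 8 for the
linkage oracle, and contamination sweeps over THCM rates 0–40% and ICM cell
rates 0–0.025 with 30 seeds — sizes at which every expected value was
derived by hand or by an independent oracle and the whole suite runs in
well under a minute per file.

## Limitations

* k is not estimated; `suggest_k()` is a heuristic, and on real data the
  dendrograms should be inspected.
* The control chart assumes approximately homoscedastic within-block
  spread on the transformed scale; blocks much smaller than the mean block
  size get conservative-to-liberal limits as described above.
* The logistic transform compresses genuine effects beyond |F| ≈ 5 as well
  as outliers; methods that need graded distinctions among very large fold
  changes should work on the classical scale with explicit outlier
  handling.
* Casewise/cellwise contamination and the N(±10, 1) contaminant are
  conventional choices, not estimates of any particular platform's artefact
  distribution; both are fully configurable.
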