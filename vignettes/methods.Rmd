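---
title: "From connectome subnetworks to regional gene co-expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From connectome subnetworks to regional gene co-expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`vhconnect` implements an analysis chain that links three levels of brain
organization: (i) a structural-connectome subnetwork whose connectivity is
reduced in one clinical group (Parkinson's disease patients with visual
hallucinations, "VH"), found by the network-based statistic; (ii) the
controllability of the linear network dynamics within that subnetwork;
and (iii) regional gene co-expression modules whose spatial profile tracks
membership in the subnetwork, followed by cell-type enrichment of those
modules' genes. Because the patient imaging and donor expression data
behind such a study cannot be redistributed, the package carries a
first-class synthetic-data module that emulates each input with planted,
known structure; every stage of the chain is validated against those
plants.

## The models, stage by stage

### Edge-wise GLM and the network-based statistic

For each upper-triangle edge, the weight is regressed on an intercept, a
0/1 group indicator, age (years) and total intracranial volume (ml) by
ordinary least squares; the statistic is the t-value of the group
coefficient. Edges that are zero in every subject are excluded (their
regression is undefined). Edges whose residual variance is at rounding
level are flagged degenerate and given t = 0.

Edges with |t| above a threshold (default 3.1, the study setting) in the
tested direction are binarized and their connected components extracted;
component size is the edge count (the original extent-type statistic — the
choice between extent and intensity is open in the source methods, and
extent is the older default). Family-wise error control comes from the
permutation distribution of the maximum component size. Because nuisance
covariates enter the model, subjects are not naively relabelled: the
package uses Freedman–Lane permutation — residuals of the reduced
(covariates-only) model are permuted and added back to the reduced-model
fit, and the full model is refit on the reconstructed data. The corrected
p-value is `(1 + #{perm max >= observed}) / (1 + n_perm)`, with `>=` ties
counted against the hypothesis, so p can never fall below
`1/(n_perm + 1)`. With seven or fewer subjects in the contrast the
permutation space is enumerated exactly (with a warning) rather than
sampled. Both directions of the contrast are run separately in the
analysis scripts, mirroring the study's negative control in the opposite
direction.

### Linear dynamics and average controllability

The dynamics are the discrete linear system `x_{t+1} = A x_t + B u_t`,
with `A` the connectome weight matrix scaled by `1/(1 + λ_max)` — the
convention of the controllability code base the field uses — which
guarantees a spectral radius below one, and `B = e_i` selecting a single
control node. Average controllability of node i is the trace of the
infinite-horizon controllability Gramian
`W_c = Σ_{τ≥0} A^τ B B' (A')^τ`, the solution of the discrete Lyapunov
equation `W_c = A W_c A' + B B'`. For symmetric `A = V Λ V'` the trace
reduces to `Σ_k V[i,k]² / (1 − λ_k²)`, so one eigendecomposition yields
all nodes at once; the τ = 0 term contributes exactly 1, so the value is
always ≥ 1. A deliberately naive truncated-sum implementation is kept in
the package as an independent oracle; tests require agreement to 1e-8 on
random stable systems up to 50 nodes (their spectral radii are capped at
0.85 so that 200 truncation terms leave a remainder far below the
tolerance). Modal controllability is intentionally not computed — the
analysis concerns average controllability only. Node ranks are dense
(ties share a rank) with ties broken by label order for reproducibility.

The association between node strength and controllability is summarised
as a Spearman correlation. The source material reports a U statistic for
this association, which is ambiguous for a correlation claim; the package
reports the correlation and leaves the U unreproduced.

### Graph topology

Density is the fraction of nonzero edges; strength is the weighted
degree. The weighted clustering coefficient is the Onnela
geometric-mean-of-triangles form on weights normalized by the maximum
weight (the Brain Connectivity Toolbox convention; the source names the
toolbox but not the formula). Characteristic path length maps weights to
lengths by the reciprocal, averages shortest-path lengths over connected
pairs, and reports the disconnected fraction instead of imputing
infinities — dense tractography-derived matrices essentially never
disconnect, and exclusion keeps the statistic finite. Whether these
metrics should be computed on normalized weights is not specified in the
source; the max-weight normalization applies to clustering only.

### Region-as-sample co-expression

Regions of the expression atlas are treated as samples, genes as
variables; the binary trait marks regions inside the detected subnetwork.
QC drops regions with more than 50% missing entries (the study excluded
three such regions), then zero-variance or mostly-missing genes, and
imputes remaining gaps with the gene median — median imputation rather
than pairwise-complete correlations keeps the downstream adjacency and
topological-overlap computations consistent.

The network is signed: `a_ij = ((1 + r_ij)/2)^β`. Whether the study's
network was signed is unstated; signed networks preserve the distinction
between positively and negatively co-regulated genes, which matters when
module–trait signs are the readout. The default β is 6, with a
data-driven selector (`pick_soft_power`) that takes the smallest power
whose signed scale-free fit R² reaches 0.8. Note a limitation of the
synthetic atlas: equal-correlation latent-factor blocks plus independent
noise are *not* scale-free, so on synthetic data the selector frequently
ends in its warning branch and the pipeline pins β = 6; on real
expression data the scan behaves as in standard co-expression practice.

Topological overlap is
`TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`; modules come from
average-linkage clustering of `1 − TOM`. The tree is cut at the height
(scanned over the upper half of the merge-height range) that maximizes
the number of clusters with at least `min_size` genes — a deliberately
simple dynamic-height cut implemented in this package — followed by the
k-means-style refinement at the eigengene level: each gene moves to the
module whose eigengene it best correlates with, genes whose best
correlation is under 0.3 become unassigned (grey), undersized modules are
dissolved into their nearest module, and the loop runs to convergence or
20 iterations. On the standard synthetic plant (4 modules × 100 genes,
within-module correlation 0.7, 180 regions, 2000 genes) this recovers the
planted partition with adjusted Rand index ≥ 0.98 on average.

Module eigengenes are first principal components of the standardized
module genes, unit variance, oriented to correlate positively with the
module mean. Module–trait association uses biweight midcorrelation with
the documented fallback to plain centring on the binary side (the MAD of
a binary vector can be zero); p-values come from the t-transform at
n − 2 df and are BH-corrected across modules. Gene significance is
|cor(gene, trait)|. Ranked gene lists for significant modules default to
gene-significance ranking (the Methods' convention in the source), with
|kME| ranking available (its Results use that variant).

### Expression-weighted cell-type enrichment

Specificity divides each gene's mean expression in a cell type by its
total across cell types. The observed statistic for a target list is the
specificity sum per cell type; the null draws, for each target gene, a
background gene from the same joint decile bin of transcript length and
GC content ("content" is read as GC content; the source does not define
it). The grid degrades gracefully (with a warning) when bins are sparse.
z is the standardized observed statistic; the one-sided enrichment p has
the same `(1 + #{null ≥ obs})/(1 + n_boot)` form and floor as the NBS
p-value, with BH correction across cell types. The desk-scale default is
10 000 bootstrap lists (the study used 100 000; the parameter is
exposed). Depletion appears only as a negative z.

## What the synthetic data emulates — and what it does not

The cohort generator draws per-edge log-normal baseline weights
(tractography streamline weights are heavy-tailed), adds subject noise
and linear age/intracranial-volume effects on the log scale, and
multiplies the planted edges by `1 − effect_size` in the VH group only —
so `effect_size = 0.5` halves them, and with zero noise the halving is
exact. Defaults (30 nodes, 20 subjects per group, a planted 15-edge
clique, effect 0.5) are the desk-scale conditions at which the
permutation test's power and error calibration are asserted; ages
(65 ± 8 y) and intracranial volumes (1450 ± 120 ml) loosely match the
cohort demographics of the motivating study. The expression generator
builds each module from a latent region factor (`gene = √ρ·f + √(1−ρ)·ε`
gives within-module correlation ρ), ties selected factors to the
standardized binary trait with a chosen sign and magnitude, and inserts
missingness completely at random plus forced bad regions to exercise QC.
The cell-type reference multiplies marker genes' expression by a fold
factor in their own type.

None of this reproduces the geometry of real brains: no spatial
autocorrelation, no distance-dependent connection weights, no donor
structure in the expression atlas, no correlated gene–covariate
relationships. Passing tests therefore demonstrate statistical
correctness of the machinery (error control, power at planted effects,
recovery of planted structure), not robustness to the spatial confounds
of real imaging-transcriptomics data.

## Numerical choices and degenerate inputs

* Matrices asymmetric beyond 1e-8 (relative) are rejected; smaller
  asymmetry is averaged away. Weights are never thresholded on load.
* Rank-deficient designs abort with the collinear columns named.
* Constant-metric comparisons (e.g. density of fully dense graphs) are
  reported as `constant` rather than tested.
* The type-I error of the NBS stage is asserted within [0.025, 0.075] at
  α = 0.05 over 200 null cohorts with 500 permutations each; problem
  sizes throughout the tests (500-permutation NBS, 500-gene compact
  atlases for replicate simulations, 5000-list bootstraps) were chosen as
  the smallest that keep the binomial noise of the asserted rates well
  inside their margins.
* A global seed is split into fixed per-stage seeds
  (`seed * 101 + offset * 7919 mod 2^31 − 1`), so toggling one stage
  never perturbs another's stream.

## Known limitations

* The dynamic-height tree cut is simpler than the hybrid dynamic tree cut
  of the reference co-expression implementation; on plants with very many
  similar-sized modules it can merge adjacent branches before refinement
  splits them.
* Biweight midcorrelation uses the binary-side fallback throughout (the
  trait is always binary here); continuous-trait bicor is not exposed.
* The imaging-to-expression region mapping is positional for synthetic
  labels (`node_k` → `region_k`) unless an explicit mapping table is
  supplied; real-data use requires that table (e.g. restricting 379
  parcels to 180 left-cortical regions).
* Permutation and bootstrap p-values inherit the usual resolution limit
  `1/(n + 1)`; significance claims near that floor need larger `n_perm`
  or `n_boot`.
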