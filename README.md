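# vhconnect

Structural-connectome subnetworks, network controllability and regional
gene co-expression — an R implementation of the analysis chain that asks
why a clinical symptom (visual hallucinations in Parkinson's disease)
maps onto a specific subnetwork of the brain's white-matter graph, and
what the regional transcriptome says about that subnetwork.

The package is written for researchers in network neuroscience and
imaging transcriptomics who want each stage of that chain as a tested,
reusable function rather than a one-off script:

1. **Network-based statistic (NBS).** Edge-wise GLM of connection weight
   on group, age and total intracranial volume; suprathreshold components
   at *t* = 3.1; family-wise error control by Freedman–Lane permutation of
   the maximum component size, *p* = (1 + #{perm max ≥ obs})/(1 + n_perm).
2. **Average controllability.** For the discrete linear dynamics
   *x*<sub>t+1</sub> = *A x*<sub>t</sub> + *B u*<sub>t</sub> on the
   stabilized connectome *A* = *W*/(1 + λ<sub>max</sub>), the trace of the
   infinite-horizon controllability Gramian
   *W*<sub>c</sub> = Σ<sub>τ≥0</sub> *A*<sup>τ</sup>*BB*′(*A*′)<sup>τ</sup>
   per control node, via the discrete Lyapunov equation — compared between
   groups inside and outside the NBS subnetwork.
3. **Region-as-sample co-expression (WGCNA-style).** Signed adjacency
   ((1 + *r*)/2)<sup>β</sup>, topological overlap, tree-cut module
   detection with k-means eigengene refinement, module eigengenes, kME,
   biweight-midcorrelation module–trait association (trait = region in
   the subnetwork) with BH correction, and gene significance.
4. **Expression-weighted cell-type enrichment (EWCE).** Specificity sums
   of a module's genes against a bootstrap null matched on transcript
   length and GC content.

Global topology (density, strength, Onnela weighted clustering,
characteristic path length) is provided for the accompanying
group comparisons, and a synthetic-data module generates cohorts,
expression atlases and cell-type references with planted ground truth so
the full chain is verifiable end to end.

## Worked example

The numbered scripts under `analysis/` run the whole chain on a synthetic
cohort (60 subjects, 30 nodes, a planted 15-edge subnetwork whose weights
are halved in the hallucinating group):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_network_topology.R
Rscript analysis/03_subnetwork_nbs.R
Rscript analysis/04_controllability.R
Rscript analysis/05_coexpression.R
Rscript analysis/06_cell_enrichment.R
```

The run prints, among other things:

```
nbs: threshold t = 3.10 (less), 5000 permutations
  component 1: 16 edges, 7 nodes, FWE p = 0.0002
opposite direction: 0 significant component(s)
planted nodes recovered: 6 / 6

strength-controllability Spearman rho (controls): 0.986
subnet_vh_vs_nonvh     mann_whitney = 360.0, p = 1.442e-06

module_set: 3 modules over 2000 genes (power 6, 1600 unassigned)
  trait-associated: ME1 (r = 0.368, q = 1.4e-06), ME2 (r = -0.308, q = 4.69e-05)
QC removed 3 region(s): region_044, region_091, region_150

-- ME2 (100 genes) --
  enriched: oligodendrocyte (z = 23.00, q = 0.0004)
```

Reading it: the NBS finds one family-wise-significant component containing
every planted node, and nothing in the opposite direction; mean average
controllability within that subnetwork is lower in the hallucinating group
(one-sided Mann–Whitney); after QC (three forced bad regions removed, as a
QC exercise) the co-expression stage recovers the planted modules, the two
trait-linked ones with their planted signs; and the down-weighted module's
ranked genes are enriched in the cell type whose markers were planted to
coincide with it. Each table lands under `results/`.

The same chain as a single call:

```r
library(vhconnect)
res <- run_pipeline(pipeline_config(seed = 1))
print(res)
```

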