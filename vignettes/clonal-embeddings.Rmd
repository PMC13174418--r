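---
title: "Clonal embeddings: model, assumptions and design choices"
author: "clonespace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal embeddings: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonespace)
```

## The problem

Lineage-coupled single-cell experiments label cells with heritable barcodes
(CRISPR scars, expressed barcode libraries) or use an endogenous barcode
(the TCR CDR3 nucleotide sequence), so that each profiled cell belongs to a
*clone* — the descendants of one labelled progenitor. A clone is therefore
an empirical distribution of cells over the expression manifold, and
questions about fate bias, clonal expansion or heritable transcriptional
states are questions about how those distributions differ between clones.
`clonespace` represents every clone by a single low-dimensional vector such
that clones occupying similar regions of expression space land close
together, and provides the downstream machinery (clustering, archetypes,
association statistics, cross-cohort alignment) that operates on that
representation.

## The model

The pipeline takes two inputs: a latent expression embedding of cells
(typically 15--30 batch-corrected PCA or scVI dimensions — batch
correction is the caller's responsibility, because any residual batch
signal propagates through the neighbourhood graph into the clonal
representation) and a per-cell clone label, possibly null.

1. **Neighbourhood counting.** An exact Euclidean kNN graph (default
   `k = 15`) is built over the clonally labelled cells only. For each cell
   we count how many of its `k` neighbours fall in each clone and sum these
   vectors over the cells of each clone, giving the $C \times C$
   co-occurrence matrix $N$ with $N_{ij}$ = neighbours from clone $j$ seen
   around cells of clone $i$. Without collapsing, row $i$ sums exactly to
   $k \cdot |i|$ — an integer identity the tests assert.

2. **Skip-gram factorisation.** Each row of $N$ is modelled as a
   multinomial draw with probabilities
   $p_{ij} = \mathrm{softmax}_j(u_i^\top V)$, the classic skip-gram with
   linear activations: input and output layers of size $C$, one hidden
   layer of size $z$ (default 10). Training minimises the multinomial
   negative log-likelihood by mini-batch SGD over the multiset of
   (target, context) events, each pair $(i, j)$ occurring $N_{ij}$ times
   and reshuffled every epoch. The input-to-hidden matrix $U$ is the clone
   embedding. Negative sampling is deliberately not implemented: its
   advantages arise with very large vocabularies and large embedding
   dimensions, and are negligible or harmful at $z \approx 10$.

3. **Poisson alternative.** Replacing the multinomial likelihood with
   independent Poissons, $\log \mathbb{E} N_{ij} = \alpha_i + \beta_j +
   u_i^\top v_j$, decouples the output units and admits alternating
   per-row/per-column Newton updates (`fit_poisson_glmpca()`). The row and
   column intercepts absorb clone-size effects, which is how we read
   "row-wise and column-wise normalisation": as intercepts in the
   log-linear mean, the convention of alternating-GLM factorisations, not
   as count pre-normalisation (a pre-scaling flag would be easy to add but
   the intercept route keeps the likelihood exact). On the two-cluster
   benchmark the two backends produce clone-distance matrices with
   Spearman correlation above 0.8, which the test suite checks.

## Optimiser choices

The paper-style training loop is plain SGD with a constant learning rate.
We add one safeguard: after every epoch the full-data mean NLL is
evaluated; an epoch that increased it is rolled back and retried at half
the learning rate (at most 10 retries, then training stops at the previous
iterate). This keeps the recorded loss history non-increasing *by
construction* — the property the optimisation-sanity checks demand at
tolerance $10^{-6}$ — while behaving identically to plain SGD whenever the
learning rate is stable. Training stops early once the per-epoch
improvement falls below `min_rel_improve` (default $10^{-5}$) of the
initial loss; epochs/learning rate defaults (100, 0.05) are exposed.
Initialisation is $\mathcal{N}(0, 0.1/\sqrt z)$ under the run seed; with a
single compute thread, reruns are bit-identical.

The Poisson fit applies one damped Newton step per row (then per column)
per outer sweep, with per-row backtracking on the row objective. Because
rows are conditionally independent given the column side, every accepted
step decreases the total deviance, so the deviance history is monotone and
the stopping rule (relative deviance change below `tol`) is well defined.

Archetypal analysis minimises $\lVert X - WBX \rVert_F^2$ with both weight
matrices row-stochastic, by alternating projected-gradient blocks with
Lipschitz step sizes (exact simplex projection, sort-based). Each
half-step is monotone, so `rss_history` never increases; initialisation is
a seeded furthest-point subset. The number of archetypes is left to the
user; `archetype_elbow()` reports RSS-versus-A diagnostics rather than
automating the choice, since selection rules (explained variance,
information criteria, bootstrap stability) are analysis decisions.

## Association statistics

Clones — not cells — are the units of replication. `clone_pseudobulk()`
averages log-normalised expression (library-size target 10,000 counts per
cell) over each clone's cells, optionally restricted to a cell type;
`clone_differential_expression()` runs two-sided Welch tests with
Welch–Satterthwaite degrees of freedom and BH correction, with the stated
convention that a gene with zero variance in both groups reports statistic
0 and p = 1. `expand_clones_by_celltype()` implements the cluster-free
variant where each clone contributes one row per cell type it spans, with
the per-cell-type mean over all clones subtracted so cell-type markers
cancel.

`supervised_pca()` solves the eigenproblem of $X^\top K X$ where $K$ is
the symmetrised binary adjacency of the clone kNN graph; with $K = I$ it
is exactly PCA (an oracle equivalence in the tests). Degree normalisation
is off by default and exposed as a flag. Moran's I uses row-standardised
weights, and inference is by seeded permutation (default) rather than the
analytic normal approximation, which is unreliable at small clone counts;
the one-sided (greater) alternative is used because the scientific
question is "more structured than chance". The clonotype-frequency test
permutes cluster labels within each tissue stratum, compares each
cluster's mean frequency to the unweighted mean of cluster means, and is
two-sided with BH correction over (cluster, stratum) pairs; its default of
100,000 permutations matches the resolution needed for small corrected
p-values.

## Cross-cohort alignment

Clonal embeddings trained independently per cohort are identifiable only
up to a linear map, so alignment needs an external reference. Per-clone
average expression acts as that reference: clones from all cohorts are
concatenated as pseudo-cells, highly variable genes are ranked batch-aware
(per-cohort variance ranks averaged), expression is scaled within cohort,
PCA is computed, and a pluggable batch-correction stage follows (identity
by default, so the pipeline has no external dependency; any
`function(coords, cohort)` can be supplied). Mutual nearest neighbours
between cohort pairs become anchors. The anchor weights are not pinned
down by any published definition we could adopt, so the package default is
**uniform weights**, with an optional inverse-distance weighting
$1/(1+d)$ — this choice is logged in the anchor tibble. Cohorts are merged
greedily in order of decreasing shared-anchor counts (group counts sum
over spanning pairs; ties break lexicographically), the smaller side
mapped onto the larger by weighted least squares
($\min \sum w \lVert L s + t - \tau \rVert^2$, closed form, ridge fallback
on rank-deficient designs). `alignment_recovery_error()` packages the
synthetic validation: affine-distorted copies of one cloud re-integrate
with relative RMS pairwise-distance error well under 5%; its `split` mode
shows what anchor mismatch costs when cohorts share no clones (roughly
10% error at the default sizes), which is why exact-copy recovery is the
contract and split recovery is diagnostic only.

## The synthetic benchmarks

Three generators emulate lineage data as 2-D "expression" spaces with
planted clonal structure; the geometry constants below are package
defaults (the benchmark design fixes compositions and totals, not
geometry), all exposed as arguments:

* **Two-cluster proportion** — Gaussian clusters at $(\pm 5, 0)$, sd 1;
  clones of 10 cells with exactly $n$ cells from cluster A for
  $n = 0 \dots 10$, 500 clones per level → 5500 clones. Truth is the
  A-proportion; recovery is scored as $|r|$ between embedding PC1 and
  truth (2 latent dimensions).
* **Three-cluster portions** — equilateral triangle of side 10, sd 1;
  clones of 15 cells in three portions of 5, each portion from A, B or C
  → 10 multiset types × 500 = 5000 clones. This benchmark probes the
  semantic geometry claim: the centroid of a mixed type should sit at the
  matching convex combination of the pure-type centroids (e.g. ABB at
  $\tfrac13$AAA $+ \tfrac23$BBB). We measure the deviation relative to
  the mean pairwise distance among pure centroids — a scale-free
  denominator chosen because the embedding origin is arbitrary — and
  observe ≤ 5% against the 15% bound.
* **Rings and crosses** — four concentric rings (radii 2, 4, 6, 8, radial
  sd 0.2) and six 8 × 0.4 crosses rotated 0°–75° in 15° steps, centred at
  (20, 0) away from the rings; 300 clones of 30 cells per structure →
  3000 clones. Subsampling to 1–50% of cells stresses sparsity; clones
  with ≥ 2 surviving cells are embedded.

Baselines treat each clone as its empirical cell distribution in the
original 2-D space and compute MMD (RBF, median-heuristic bandwidth,
biased estimator), debiased Sinkhorn divergence (squared-Euclidean cost,
$\varepsilon = 0.05 \times$ mean pairwise squared distance, log-domain
scaling with $\varepsilon$-annealing and a symmetric fixed-point for the
self terms), energy distance (V-statistic convention, so identical samples
give exactly zero), and a cluster-composition distance (Leiden at
resolution 1 on the cell graph, Euclidean between proportion vectors).
Distance methods feed `best_ari()` directly as kNN inputs; every method is
scored by its best ARI over Leiden resolutions 0.1–2.0 in steps of 0.1
(20 values).

What these simulations do **not** emulate: dropout and depth variation in
counts (cells are points, not transcriptomes), batch structure, doublets,
barcode collisions or ambiguous lineage assignments, and cell-state
continua (structures are crisp). Passing them shows the estimator
recovers planted compositional structure at realistic sparsity — not that
any particular biological claim holds on real data.

## Numerical conventions and degenerate inputs

* kNN ties (duplicated coordinates) break toward the lower cell index;
  exact brute-force neighbours are used (the contract allows an
  approximate backend above 50k cells, which we have not needed).
* The null clone label is `NA`; it is never counted in $C$. Duplicate
  cell ids are an error, never merged. Labelled cells missing from the
  embedding are dropped with a warning.
* Collapsed ("masked") cell groups become extra context columns only;
  clones entirely inside a masked group lose their row with a warning,
  and the row-sum identity still holds for retained rows.
* An all-zero co-occurrence matrix, a constant vector handed to Moran's
  I, an empty pseudobulk mask, and Leiden with $k \ge C$ are errors with
  typed condition classes.
* Sinkhorn iterations stop when the entropic cost stabilises to $10^{-8}$
  relative; non-convergence at `max_iter` raises an error rather than
  returning a silent partial value. The divergence is clamped at zero
  against $10^{-15}$-scale float noise.
* AIRR input requires `cell_id`, `locus`, `junction`; the `productive`
  flag is **not** filtered on by default (flag available). Cells with more
  than one distinct TRB junction are excluded; full TRA sets must match.
  Ambiguous or multi-barcode cells in non-TCR data are represented as
  null labels.

## Problem sizes used in the checks

The automated checks run the full 5500-clone two-cluster benchmark for
proportion recovery; the three-cluster benchmark at 50 clones per type for
midpoint geometry (3 seeds); rings-and-crosses at 60 clones per structure
with 10% subsampling for the sparsity comparison (3 seeds); and smaller
fixtures elsewhere. These sizes are the package's validation conditions:
large enough for the geometry to be stable, small enough that the whole
suite runs on a laptop core in minutes.

## Known limitations

* H5AD containers are not read directly; use the TSV/CSV cell-table or
  MTX loaders, or export from your single-cell framework.
* The skip-gram softmax is exact (no negative sampling or hierarchical
  softmax), so training cost grows with $C^2$ events; the Poisson backend
  is the intended route for very large clone sets.
* Anchor-based alignment assumes cohorts share enough biology for
  expression MNNs to be meaningful; disconnected cohorts are left
  unaligned and reported rather than forced.
* Archetype number selection, UMAP layouts and trajectory inference on
  the clone space are intentionally out of scope.
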