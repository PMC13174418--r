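# clonespace

Clonal embeddings from lineage-coupled single-cell data.

In lineage-tracing and TCR-sequencing experiments every profiled cell
carries a clone label — a heritable barcode or a CDR3 nucleotide sequence —
so a *clone* is an empirical distribution of cells over the expression
manifold. `clonespace` turns each clone into a single low-dimensional
vector: it builds a k-nearest-neighbour graph over labelled cells in a
latent expression space, aggregates it into the clone-by-clone neighbour
co-occurrence matrix *N* (entry *N<sub>ij</sub>* = neighbours from clone
*j* observed around cells of clone *i*; each row sums to *k* · clone
size), and factorises *N* with a skip-gram multinomial model

&nbsp;&nbsp;&nbsp;&nbsp;p<sub>ij</sub> = softmax<sub>j</sub>(u<sub>i</sub><sup>⊤</sup>V),&nbsp;&nbsp;
minimise&nbsp; Σ<sub>ij</sub> N<sub>ij</sub> (−log p<sub>ij</sub>),

whose input-to-hidden weights *U* (C × z, default z = 10) are the clone
embedding, or with the scalable Poisson log-linear alternative
log E N<sub>ij</sub> = α<sub>i</sub> + β<sub>j</sub> +
u<sub>i</sub><sup>⊤</sup>v<sub>j</sub> fitted by alternating Poisson
regressions. Clones with similar cell-state distributions land close
together, and mixed clones sit between the pure behaviours they combine.

On top of the embedding the package provides clone-graph Leiden
clustering, archetypal analysis (convex-polytope fitting with
row-stochastic weights), clone-level pseudobulk differential expression
(Welch + BH), graph-aware supervised PCA, Moran's I permutation testing,
clonotype-frequency permutation tests, TCR clonotype derivation from AIRR
tables, mutual-nearest-neighbour alignment of independently trained
cohort embeddings, and a synthetic benchmark suite with
distribution-distance baselines (MMD, Sinkhorn divergence, energy
distance, cluster composition).

Intended users: computational biologists analysing lineage-coupled
scRNA-seq (barcoded differentiation systems, TCR-sequenced T cell
cohorts) who need clone-level representations rather than per-cell ones.

## Worked example

Embed the rings-and-crosses benchmark (ten planted structures, clones of
30 cells) and recover the structures by clustering the clone space:

```r
library(clonespace)

ds  <- simulate_rings_crosses(seed = 7, per_structure = 30)
ds
#> <synthetic_clones> 9000 cells, 300 clones (rings_crosses)

emb <- embed_synthetic(ds, z = 10, k = 15, backend = "skipgram",
                       min_clone_size = 3, seed = 7, epochs = 60)
emb
#> <clone_embedding> 300 clones x 10 dims (skipgram)

truth <- setNames(ds$clone_truth$truth, ds$clone_truth$clone)
best_ari(emb, truth, seed = 7)
#> <benchmark_result> best ARI 1.000 at resolution 0.1 (20 resolutions)
```

The embedding separates all ten structures perfectly (adjusted Rand index
1 against the planted labels over the 0.1–2.0 resolution sweep). For real
data, start from `load_inputs()` (TSV/CSV cell table with latent
coordinates and a clone column, optional MTX counts), or
`derive_tcr_clonotypes()` for AIRR rearrangement tables, then
`clone_cooccurrence() |> fit_skipgram() |> clone_embedding()`. Results are
tibbles or carry `tidy()`/`glance()`/`autoplot()` methods throughout. A
command-line wrapper with `embed`, `cluster`, `archetypes`, `associate`,
`align`, `simulate` and `benchmark` subcommands is installed at
`inst/cli/clonespace`.

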