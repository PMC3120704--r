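# ieaclust

Independent Enrichment Analysis of gene lists via annotation clustering.

## The problem

A list of differentially expressed genes usually mixes several distinct
biological programmes, each driven by its own regulators. Standard
over-representation analysis tests every annotation against the whole list,
so themes confined to a subset of genes are diluted away, and it gives no
hint of *which regulator* drives *which process*. `ieaclust` addresses both
problems by clustering the list **twice** — once on functional annotations
(e.g. Gene Ontology terms), once on regulatory annotations (e.g.
transcription-factor target sets) — and then cross-examining each cluster
with the *other* annotation system.

## The method

Each annotation system is a binary incidence matrix `V` (genes × annotations,
`v_ij = 1` iff gene *i* carries annotation *j*). For every number of clusters
k = 1..K the matrix is factorized as `V ≈ WH` with non-negative `W`
(genes × k) and `H` (k × annotations) by Lee–Seung multiplicative updates
minimizing the generalized Kullback–Leibler divergence; genes are assigned to
the component with the largest loading. The independent per-k partitions are
stacked into a **non-nested cluster tree** whose adjacent levels are linked
by the best phi correlation of cluster memberships.

The number of clusters is scored with AIC under a per-cluster Bernoulli
model: for cluster *c* and annotation *j* the ML rate is
`θ(c,j) = (ones in c)/|c|`, and `AIC = 2p − 2 lnL` with one parameter per
(nonempty cluster × annotation). Because annotations spread randomly across
clusters swamp this score, a **dAIC** variant first filters out every
dimension whose per-dimension AIC never improves over the unclustered list in
any solution with more than two clusters, then rescores all levels on the
retained dimensions.

Each cluster is then tested for annotation over-representation against the
whole list with the one-sided Fisher exact test (hypergeometric tail),
BH-FDR corrected:

* **DEA** (dependent enrichment analysis) — testing the same system that
  produced the clusters; descriptive only, since the test variable formed
  the cluster.
* **IEA** (independent enrichment analysis) — testing the *other* system;
  statistically interpretable, and the package's point: it names the
  regulators putatively controlling each functional cluster (and vice
  versa).
* **Inter-correlation** — Fisher tests of membership overlap between every
  cluster pair across the two trees.

A planted-partition generator of coupled binary annotation systems makes
power and error-control properties testable without external databases.

## Worked example

```r
library(ieaclust)
set.seed(1)
d <- generate_annotation_systems(n_genes = 120, k_true = 3, seed = 7)
res <- run_pipeline(names(d$partition), d$system_one, d$system_two,
                    out_dir = "results_demo", k_max = 5, seed = 7, restarts = 5)
#> seed 7; 120 list genes; GO: 120 genes x 29 annotations; TF: 120 genes x 29 annotations
#> GO tree: 23/29 dimensions retained by dAIC filter; best AIC level 3, best dAIC level 3
#> TF tree: 24/29 dimensions retained by dAIC filter; best AIC level 3, best dAIC level 3

glance(res$tree_one)
#> # A tibble: 1 × 7
#>   system n_genes n_annotations k_max n_retained_dimensions best_aic_level best_daic_level
#>   <chr>    <int>         <int> <int>                 <int>          <int>           <int>
#> 1 GO         120            29     5                    23              3               3

adjusted_rand_index(res$tree_one$levels[[3]]$assignment, d$partition)
#> [1] 0.9021476

head(res$intercorrelation, 3)
#> # A tibble: 3 × 8
#>   cluster_a size_a cluster_b size_b overlap universe_size    p_raw    p_fdr
#>       <int>  <int>     <int>  <int>   <int>         <int>    <dbl>    <dbl>
#> 1         3     42         3     40      40           120 7.52e-30 6.76e-29
#> 2         1     38         1     40      38           120 2.90e-29 1.30e-28
#> 3         2     40         2     40      38           120 2.15e-26 6.46e-26
```

Both trees select the planted k = 3 by dAIC; the level-3 partition matches
the planted clusters (adjusted Rand index 0.90); the inter-correlation table
pairs each functional cluster with its regulatory counterpart at vanishing
FDR. `dplyr::filter(res$enrichment, mode == "IEA", p_fdr < 0.1)` lists which
second-system annotations are independently enriched in which first-system
cluster — the analysis result a user reads first. `autoplot(res$tree_one)`
draws the cluster tree; `tidy(res$tree_one)` returns the per-level
memberships.

A command-line wrapper with `simulate` and `run` subcommands is installed at
`system.file("scripts", "ieaclust.R", package = "ieaclust")`.

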