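# grnevo — evolutionary structure of gene regulatory network communities

`grnevo` is an R package for asking how the evolutionary history of genes is
organized on a gene regulatory network (GRN). It is written for
computational/evolutionary biologists who have (a) a weighted, partially
directed gene network as an edge list, and (b) per-gene evolutionary rates
(ER, nonsynonymous substitutions per amino-acid site per billion years) and
phylostratigraphic ages (an integer stratum 0 = oldest … 12 = youngest) —
or the raw material to compute them (amino-acid alignments plus a dated
phylogeny; ortholog presence/absence over ordered clades).

The package tests three linked predictions:

1. **Assortativity** — interacting genes have similar ERs and ages. The
   statistic is the width (SD) of value differences over directed edges
   j → i, compared with degree-preserving double-edge-swap randomizations
   of the network: a strongly negative z-score means like interacts with
   like.
2. **Community homogeneity** — communities found by maximizing directed
   weighted modularity
   Q = (1/m) Σᵢⱼ [Wᵢⱼ − sᵢᵒᵘᵗ sⱼⁱⁿ / m] δ(cᵢ, cⱼ)
   are significantly hot/cold (ER) or young/old (age) relative to 300
   equal-size random gene sets, at one-tailed p < 10⁻³.
3. **Core–periphery placement** — old, cold genes and gene groups are
   central. Gene-level: degree, PageRank, betweenness vs ER/age.
   Group-level: the package's set efficiency and interset efficiency,

   E_M = (1/(|M|(|M|−1))) Σ_{i≠j∈M} 1/dᵢⱼ,
   E_IJ = (Σ_{i∈I, j∈J, i≠j} 1/dᵢⱼ) / (|I||J| − |I∩J|),

   where dᵢⱼ is the hop distance from j to i on the *full* network
   (paths may leave the set), unreachable pairs contribute 0, and
   E_II = E_I exactly. A cumulative SE curve over genes ranked coldest →
   hottest (windows 500, 510, … genes, with 100 shuffled-order controls)
   shows whether the coldest genes form an efficiently connected core.

A synthetic-data generator with planted core–periphery community structure
(`generate()` / `null_generate()`) makes every stage testable end to end,
and a hypergeometric + Benjamini–Hochberg enrichment step stands in for
web-based functional annotation of communities.

## Worked example

```r
library(grnevo)

# synthetic GRN: 4 communities of 75 genes on a core-periphery axis,
# ER and age increasing core -> periphery
bundle <- generate(synth_config(seed = 42))
bundle$network
#> gene_network: 300 nodes, 2335 edges (1184 directed, 1151 undirected), total directed weight 3486

# communities by directed weighted modularity
part <- detect_communities(bundle$network, seed = 42)
part
#> community_partition: 300 genes in 4 communities (sizes 75/75/75/75), Q = 0.4783

# edge-level ER assortativity against 200 degree-preserving rewirings
edge_diff_test(bundle$network, bundle$annotation, "er", n_random = 200, seed = 1)
#> edge_diff_result (er): 3486 edge differences, width 0.9906, null 1.461 +/- 0.015, z = -31.26, p <= 0.00498

# the hottest planted community against 300 equal-size random gene sets
er <- annotation_values(bundle$annotation, "er")
hot <- bundle$partition$communities[[
  which.max(sapply(bundle$partition$communities, function(cc) mean(er[cc])))]]
group_mean_test(bundle$network, bundle$annotation, hot, "er",
                seed = 1, name = "hottest community")
#> group_stats 'hottest community' (er, n = 75): mean 2.946, diff 1.276, p = 1.11e-34 -> hot; KS = 0.617 (p = 0)

# efficiency: the whole network vs the hot (peripheral) community
global_efficiency(bundle$network)
#> efficiency_result: 0.404686 (89700 contributing, 0 unreachable ordered pairs)
set_efficiency(bundle$network, hot)
#> efficiency_result: 0.50509 (5550 contributing, 0 unreachable ordered pairs)

# group-level placement: mean PageRank falls with mean age
ct <- compute_centralities(bundle$network)
group_centrality_correlation(bundle$sets$sets, ct, bundle$annotation,
                             "pagerank", "age")
#> correlation_report (group, age, n = 12): Pearson R = -0.789 (p = 0.00229), Spearman rho = -0.785 (p = 0.00251)
```

Reading the numbers: the rewiring z of −31 says interacting genes have far
more similar ERs than degree-matched chance; the hottest community's mean
ER sits 1.28 above the random-set mean (one-tailed p ≈ 10⁻³⁴, far beyond
the 10⁻³ labeling threshold); and across the twelve planted annotation
groups, mean PageRank falls with mean age (R = −0.79) — old groups are
central, young groups peripheral.

The same stages run from the shell via the launcher in `inst/scripts/`:

```sh
Rscript inst/scripts/grnevo synth --seed 42 --out demo/
Rscript inst/scripts/grnevo communities --edges demo/edges.tsv --out demo/comm.tsv --seed 42
```

or end to end with `run_all()` / the `run-all` subcommand and a flat
key=value config file, which writes community, enrichment, centrality,
correlation, edge-difference, SE-curve and IE-matrix TSV reports, each
stamped with the seed and a config hash.

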