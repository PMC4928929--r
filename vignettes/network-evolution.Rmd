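---
title: "Evolutionary structure of gene-network communities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary structure of gene-network communities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnevo)
```

# The question grnevo addresses

Genes do not evolve as independent units: regulatory interactions couple the
fate of a gene to that of its interaction partners. On a gene regulatory
network (GRN) this predicts measurable structure — interacting genes should
have similar evolutionary rates and ages, communities of genes should be
evolutionarily homogeneous, and (under a duplication-driven growth picture)
old, slowly evolving genes should sit near the topological core of the
network while young, fast-evolving genes sit at the periphery.

grnevo implements the full analysis needed to test these predictions on a
weighted, partially directed GRN: per-gene evolutionary annotation,
community detection by directed weighted modularity, randomization nulls at
the edge and group level, centrality analysis, and set-level efficiency
measures that quantify how close a group of genes is, within itself or to
another group.

# Data model

A network is a set of gene symbols with weighted edges, each either
strictly directed or undirected. Internally every undirected edge becomes a
pair of reciprocal directed edges sharing one weight; all distance,
centrality, modularity and efficiency computations run on this *directed
expansion*. Edge weights are confidence scores, not lengths, so distances
default to unweighted hop counts; a `weighted = TRUE` mode (length =
1/weight) exists on the distance-based functions but is not the default.

Annotations attach to gene symbols (uppercased, whitespace-stripped; no
alias resolution):

* **Evolutionary rate (ER)**, in nonsynonymous substitutions per amino-acid
  site per billion years. Low = "cold", high = "hot". Computed from an
  amino-acid multiple alignment and a dated phylogeny: the rate of one
  alignment column is the number of different residues there divided by the
  total time span of the tree (the sum of its branch lengths, in By), and
  the gene's ER is the mean over informative columns. The
  `distinct_minus_one` convention (substitution count rather than residue
  count) is selectable; the default counts distinct residues, which gives a
  strictly positive floor for any variable column and is consistent with a
  small positive minimum ER across genes. Gap and ambiguity characters
  (`- . * X B Z`) never count as residues, and columns with fewer than two
  residues are skipped as uninformative.
* **Age**, an integer stratum 0–12: the index of the earliest-branching
  clade (0 = oldest, 12 = the human clade) whose genome contains an
  ortholog, taken from a 13-column presence/absence profile over clades
  ordered oldest to youngest.

# Communities

`directed_modularity()` scores a partition by
$$Q = \frac{1}{m}\sum_{ij}\Big[W_{ij} - \frac{s_i^{out}s_j^{in}}{m}\Big]\delta(c_i,c_j),$$
the directed, weighted generalization of modularity, where $s^{out}, s^{in}$
are weighted out-/in-strengths and $m$ the total weight of the directed
expansion. The trivial one-community partition scores exactly 0 on every
graph, which the tests assert.

`detect_communities()` maximizes this objective with a Louvain-style greedy
scheme: repeated local-move sweeps over the nodes (sweep order shuffled by
the seed), followed by aggregation of communities into supernodes, until no
sweep improves $Q$. Ties between candidate communities are broken by the
lowest community id, and community lists are ordered by size with
lexicographic tie-breaks, so a fixed seed yields a byte-identical partition.
We deliberately implement the optimizer in the package rather than
delegating it, because no installed library optimizes *directed* weighted
modularity; the independent `igraph::modularity(..., directed = TRUE)`
evaluation is used in the test suite as an oracle for the objective itself.

# Null models

Two randomizations, matching the two levels of the analysis:

* **Degree-preserving rewiring** (`rewire()`, used by `edge_diff_test()`).
  Double-edge swaps are proposed separately within the strictly directed
  and the undirected edge class; proposals creating self-loops or duplicate
  pairs are rejected, so every node keeps its exact in- and out-degree.
  Attempts (not accepted swaps) are counted; the default is 10 times the
  edge count. The statistic is the width (standard deviation) of
  $\mathrm{value}_j - \mathrm{value}_i$ over directed edges $j \to i$: if
  interacting genes have similar ERs or ages, the real width falls far
  below the rewired widths, giving a large negative z-score. The empirical
  p-value uses the $(r+1)/(n+1)$ estimator, so it is bounded away from
  zero at $5\times10^{-5}$ for 20,000 replicates and at about
  $5\times10^{-3}$ for the package's scaled default of 200.
* **Equal-size random gene sets** (`group_mean_test()`). A group's mean ER
  or age is compared with 300 sets of the same size drawn without
  replacement from the network's annotated genes. The one-tailed p-value is
  a normal tail computed from the null set-means' mean and standard
  deviation: an empirical rank over 300 draws could never reach the
  extremely small values this test is expected to produce, so the normal
  approximation is the documented choice. Draws are made from the sorted
  value vector, which makes the p-value exactly invariant under relabeling
  of genes. Groups significant at $\alpha = 10^{-3}$ are labeled
  hot/cold (ER) or young/old (age; a *larger* index is *younger*);
  otherwise "average". A two-sample Kolmogorov–Smirnov statistic against
  all annotated genes is reported alongside as a distribution-level
  summary.

`shuffled_community_control()` permutes genes across communities while
keeping each community's size, the control showing that community-level
homogeneity and enrichment are not size artifacts.

# Efficiency measures

For distances $d_{ij}$ (from $j$ to $i$, hop counts on the full network):

$$E_{global} = \frac{1}{n(n-1)}\sum_{i \ne j}\frac{1}{d_{ij}}, \qquad
  E_M = \frac{1}{|M|(|M|-1)}\sum_{i \ne j \in M}\frac{1}{d_{ij}}, \qquad
  E_{IJ} = \frac{\sum_{i \in I, j \in J, i \ne j} 1/d_{ij}}{|I||J| - |I \cap J|}.$$

Unreachable pairs contribute 0 to the numerator while remaining in the
denominator — the convention that keeps every value in $[0,1]$ on
unweighted networks. Set efficiency measures how close a gene set is
*through the whole network*: shortest paths may pass outside the set.
Interset efficiency is its asymmetric two-set generalization; the overlap
term in the denominator makes $E_{II} = E_I$ an exact identity, which the
tests verify bitwise. `ie_matrix()` orders groups by mean age (oldest
first) and reports the full asymmetric matrix, entry (row $i$, column $j$)
being the efficiency from group $j$ to group $i$.

`cumulative_se_curve()` ranks annotated genes from coldest to hottest (or
oldest to youngest; ties broken by symbol), then reports the SE of the
first 500 genes, the first 510, and so on in steps of 10 until all genes
are included, against the mean ± one standard deviation of 100 curves with
shuffled gene order. The final window contains every gene in both the real
and every control curve, so the curves coincide there exactly — a built-in
sanity check. The seed governs only the control shuffles.

# Enrichment

As a transparent stand-in for web-based functional annotation tools,
`enrich_communities()` scores every (community, gene set) pair with an
upper-tail hypergeometric p-value and applies Benjamini–Hochberg correction
within each community's battery of tests, reporting at most the top three
sets below an adjusted-p threshold of $10^{-4}$ per community. No EASE-style
score deflation and no fuzzy clustering of annotation terms is attempted;
results are therefore comparable in spirit, not in exact numbers, to
DAVID-style reports.

# The synthetic generator

`generate()` produces networks whose statistical structure matches what the
analysis assumes in real data, so every stage can be validated end to end
without any download:

* a stochastic block model of 4 communities × 75 genes (defaults), with
  within-community edge probability 0.15;
* communities placed on a one-dimensional core–periphery axis; the
  between-community probability interpolates log-linearly from 0.05 (core)
  to 0.005 (far periphery) with the pair's *mean* axis position, so the
  core community is denser to every other community than any more
  peripheral community is — this is what makes old/cold communities come
  out central under PageRank;
* half the edges strictly directed (random orientation), half undirected,
  mirroring a partially directed GRN;
* per-community ER centers 0.5/1/2/3 (gene-level SD 0.5, clamped at 0) and
  age centers 2/5/8/11 (SD 1.5, rounded and clamped to 0–12), increasing
  core to periphery — this plants both edge-level assortativity and
  group-level mean shifts;
* three annotation sets per community (mirroring a top-three-groups-per-
  community report), each sampling 40% of its home community with 5%
  leakage from outside.

`null_generate()` returns the identical network with the (ER, age) pairs
permuted across genes — the calibration case in which edge-difference
z-scores must be near zero and group labels "average".

What the generator does *not* emulate: degree heterogeneity beyond the
block model (real GRNs are heavy-tailed), duplication–divergence growth,
weight heterogeneity (all weights are 1), and annotation noise structure
beyond Gaussian scatter. Passing tests therefore demonstrate correctness
and sensitivity of the machinery under planted structure, not biological
conclusions about any real network.

# Numerical and design choices

* **Hop-count distances.** In networks of this kind genes are typically
  separated by a handful of directed steps; edge weights are detection
  confidences, so treating them as lengths would distort distances. The
  weighted mode exists for sensitivity analyses only.
* **PageRank damping 0.85**, uniform teleport, weights as transition
  weights row-normalized by out-strength. Betweenness uses hop-count
  shortest paths, normalized by $(n-1)(n-2)$. Degree centrality is
  $(k^{in}+k^{out})/(2(n-1))$, counting each undirected edge once per
  direction.
* **Determinism.** Every stochastic operation takes a seed; sweep order,
  control shuffles and random sets derive from it; all remaining order
  ties break lexicographically by gene symbol. Pipeline outputs carry the
  seed and a configuration hash in their headers, and a rerun with the
  same configuration is byte-identical.
* **Degenerate inputs.** Self-loops are rejected at construction;
  singleton sets have no set efficiency (error); two identical singleton
  sets make the interset denominator zero (error); constant vectors make
  correlations undefined (flagged, not silently zero); an all-gap
  alignment column is skipped as uninformative; a null-width distribution
  with zero variance flags the z-score as undefined.
* **Problem sizes.** The test suite and the acceptance script run the
  replicate counts the package documents as scaled defaults — 200
  rewirings, 300 random sets, 100 shuffled-order controls — on the default
  300-gene generator output, and use a 6 × 200-gene core–periphery
  configuration wherever the conventional 500-gene first window of the
  cumulative SE curve is exercised (the default configuration has only 300
  genes, so a 500-gene window would be meaningless there). Paper-scale
  counts (e.g. 20,000 rewirings) are a single configuration value away.

# Limitations

* The hypergeometric + BH enrichment is a stand-in, not a reimplementation
  of DAVID; fuzzy term clustering is out of scope.
* The normal-tail group p-value is an approximation whose far-tail values
  should be read as orders of magnitude, not exact probabilities.
* ER computation requires the user to supply an alignment and a dated tree
  (or a precomputed ER table); ortholog detection, alignment and phylogeny
  estimation are out of scope.
* Community detection is greedy; it is deterministic given a seed but, like
  all modularity maximizers, not guaranteed to find the global optimum and
  subject to modularity's resolution limit.
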