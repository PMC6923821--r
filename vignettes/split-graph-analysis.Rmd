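---
title: "Split-graph analysis of microbiome co-occurrence and function"
author: "splitgraphr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-graph analysis of microbiome co-occurrence and function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitgraphr)
```

## The model

A split graph is a graph whose vertices partition into two disjoint sets:
a set that may form a clique and an independent set with no internal
edges. `splitgraphr` uses this structure to integrate two kinds of
microbiome evidence in one object. Taxa sit on the clique side, joined by
*clique edges* whenever their abundances co-vary strongly across samples;
KEGG modules (functional units made of KO gene families) sit on the
independent side, joined to taxa by *cross edges* whenever a large
fraction of the module's KOs co-varies with that taxon. Because modules
are never joined to each other, every clique of the mixed graph contains
at most one module node. A high-weighted maximal clique therefore reads
directly as a biological statement: a group of mutually co-occurring taxa
together with (at most) one functional module associated with all of
them.

The pipeline has four stages.

**1. Co-occurrence network.** Within one sample group, Spearman's ρ is
computed for every unordered taxon pair, with average ranks on ties.
Edges with |ρ| > `rho_min` and Benjamini–Hochberg adjusted p < `q_max`
are retained, keeping ρ's sign. Spearman is used because abundance tables
are heavy-tailed and the statistic is invariant to monotone per-feature
transforms, so raw counts and per-feature rescalings give identical
networks.

**2. KO density.** The same correlation machinery links taxa to
individual KOs, with its own BH family over all (taxon, KO) pairs tested
together. For taxon $B_j$ and module $M_i$ the association strength is
the KO density

$$\mathrm{density}_j^i \;=\; \frac{\#\{\text{KOs in } M_i
\text{ correlated with } B_j\}}{\#\{\text{KOs in } M_i\}},$$

an exact rational in $[0,1]$ computed by `module_density()`. Both
positively and negatively correlated KOs count toward the numerator: the
density measures how much of the module tracks the taxon, not the
direction. Associations with density ≥ `density_min` become cross edges.

**3. Clique extraction.** `enumerate_maximal_cliques()` runs pivoting
Bron–Kerbosch on the full mixed graph; the independent-set property makes
special-casing of module nodes unnecessary. `rank_cliques()` scores each
clique by the sum (default) or mean of |ρ| over internal edges plus the
cross-edge densities to its module, and orders deterministically
(weight, then size, then taxon labels). `export_graphml()` writes the
graph with node/edge class attributes and clique membership for
visualization in Cytoscape or igraph.

**4. Shared-ancestor proportions.** For two groups' networks and an
ancestor rank (family, order, class, phylum), each edge whose endpoints
both carry that rank contributes to $n$, and to $x$ when the two
lineages agree there. The difference in $x/n$ between groups is tested by
the pooled two-proportion z statistic

$$z = \frac{\hat p_1 - \hat p_2}
{\sqrt{\hat p(1-\hat p)\left(\frac{1}{n_1}+\frac{1}{n_2}\right)}},
\qquad \hat p = \frac{x_1+x_2}{n_1+n_2},$$

two-sided against the standard normal, with no continuity correction.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `rho_min` | 0.6 | minimum \|ρ\| for a retained edge (unitless, in [0,1)) |
| `q_max` | 0.05 | BH-adjusted p ceiling, per analysis family |
| `density_min` | 0.6 | minimum KO density for a cross edge |
| `density_cmp` | `"ge"` | boundary comparison for the density threshold |
| `scheme` | `"sum"` | clique weight aggregation (`"mean"` is scale-free) |
| `keep_negative` | `TRUE` | retain negative-ρ edges (sign kept, magnitude weighted) |

The correlation thresholds are strict (`>`, `<`) exactly as conventionally
quoted. The density boundary is inclusive by default because associations
landing exactly on 0.60 are conventionally reported as retained; `"gt"`
restores the strict reading. The `sum` weighting favors larger
informative cliques; `mean` removes the size advantage.

Thresholding by |ρ| rather than ρ is deliberate: strong negative
co-exclusions are as informative as co-occurrences, and they survive with
their sign as an edge attribute (`rho_sign` in GraphML) while their
magnitude contributes to clique weights. Set `keep_negative = FALSE` for
a positive-only network.

## FDR families and p-values

Each call to `spearman_all_pairs()` or `taxon_ko_links()` is one BH
family: all pairs tested within one group × rank analysis. Families are
not pooled across groups, because each group's network is an independent
analysis. p-values use the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom, documented
and tested; for very small n (< 10) an exact permutation p-value is
available via `p_method = "permutation"`. Features constant across the
sample subset have undefined ρ; such pairs are emitted with `rho = NA`,
excluded from the BH family, and counted in `n_constant_pairs`.

## Input conventions and edge cases

Abundance tables default to features-as-rows (the QIIME/PICRUSt
convention) with a transpose flag; delimiters are sniffed (tab, then
comma) with an override. Abundances must be finite and non-negative;
correlations run on whatever scale is supplied. An optional per-sample
relative-abundance normalization flag exists and defaults to off —
Spearman is invariant to per-feature monotone transforms but *not* to
per-sample renormalization, so the scale is an explicit analysis
decision.

Greengenes-style lineage strings (`k__...; p__...; ...`) parse into a
fixed kingdom→species rank order; an empty payload (`g__`) is an absent
rank, not an empty name. `aggregate_to_rank()` sums features sharing a
rank value and pools rank-less features into an explicit `"unassigned"`
sentinel. Edges incident to that sentinel, or to endpoints lacking the
tested rank, are excluded from both $x$ and $n$ in the ancestor test: an
unconfirmed lineage cannot witness a common ancestor. When the pooled
proportion is 0 or 1 the z denominator vanishes; the test reports z = 0
with a `degenerate` flag rather than NaN. Significance stars in
`compare_groups()` are annotations only; no multiplicity correction is
applied across ranks.

Maximal cliques of size 1 are suppressed by default. Besides the mixed
enumeration, `scope = "taxa"` reports bacteria-only maximal cliques,
which can be maximal among taxa yet extendable by a module node; strict
completeness (the module adjacent to *every* member) is the default
reading everywhere, as the weaker "adjacent to some members" variant is
already visible through the taxa-scope report combined with the cross
edges.

## The synthetic-data generator

`synth_generate()` emulates the statistical structure the pipeline
assumes, not sequencing itself. Taxon log-abundances of a planted block
are `strength · F + N(0, noise_sd)` with a fresh standard-normal factor
`F` per block, sample and group; other taxa are independent standard
normals; abundances are exponentiated, giving log-normal marginals
(standard for microbiome abundance data). Each planted coupling drives
`f · module_size` KOs as a monotone (log-linear, slope 1) function of the
driving taxon plus noise, so Spearman recovery is exact in the noiseless
limit. The lineage plan gives block members a shared family — planted
co-occurrence coincides with shared ancestry, as it typically does in
real communities — with remaining taxa in distinct families, families
paired into orders, one class and phylum.

Reference conditions are fixed at 30 samples per group (CDT/CDS/HCS), 20
taxa, two blocks of three taxa at strength 0.95, noise SD 0.1, 60 KOs in
8 modules, and couplings at fractions 0.8 and 0.6 on size-5 modules
(fractions are validated to resolve to whole KOs). Under these
conditions the pipeline recovers essentially all planted edges and
couplings, and with strength 0 the retained-edge fraction stays at the
FDR level — both checked in the test suite (20 seeds for recovery, 200
replicates for the null, 500 random graphs ≤ 12 nodes against an
exhaustive clique oracle, 200 random end-to-end pipelines for graph
validity; sizes chosen so the full suite runs in well under a minute per
property).

What the generator does **not** emulate: compositional closure and
sequencing-depth variation (no rarefaction modeling), taxon-taxon
interactions beyond shared linear factors, overdispersed count noise, and
the correlation structure PICRUSt induces among KOs of the same genome.
Passing tests therefore demonstrate correctness of the statistical
machinery and recovery under the stated generative model — not robustness
to compositional artifacts, for which dedicated methods (e.g.
SparCC-style approaches) exist and are out of scope here.

## Numerical and design notes

- Canonical edge ordering (`feature_a < feature_b` lexicographically) and
  sorted node sets make every output invariant under sample and feature
  reordering; tests assert this.
- Clique enumeration is exponential in the worst case, but thresholded
  co-occurrence networks at family/genus level are small and sparse;
  graphs with hundreds of nodes remain practical.
- The taxon–KO association stage uses the same `q < 0.05` retention rule
  as the taxon–taxon stage; the two stages differ only in their test
  family.
- KO density is monotone non-decreasing in the link set and equals 1 iff
  every module KO is linked; `all_densities()` omits (taxon, module)
  pairs with no linked KO.
- Ranked ties are broken by size then by the sorted taxon-label string,
  so identical inputs always produce byte-identical reports (the CLI's
  determinism test re-runs a full stage and compares files).

## Limitations

Spearman correlation on relative abundances can produce spurious
negative associations through compositional closure; interpret negative
edges with that caveat. The KO density treats a module's KOs as
exchangeable — no weighting by reaction essentiality or module topology.
The ancestor test conditions on the retained networks: it tests edge
composition, not differential abundance. And module attachment is only as
good as the KO→module map supplied; stale maps silently shrink densities.
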