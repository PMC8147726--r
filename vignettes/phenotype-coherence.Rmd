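---
title: "Methods: phenotype co-occurrence, link communities and functional coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype co-occurrence, link communities and functional coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolink)
```

# The model

`phenolink` treats a disease catalogue as a layered annotation network:
diseases in the middle, phenotypes on one side, genes on the other. Two
working assumptions drive everything:

* phenotypes that repeatedly co-occur across diseases of a class reflect
  genuine co-morbidity rather than annotation noise, and
* groups of co-occurring phenotypes whose associated genes converge on a
  common cell function point at a shared pathomechanism.

Neither assumption is testable on a single disease; both become testable
across a corpus, which is why every statistic in the package counts
*diseases* (presence/absence) and never annotation rows — duplicated rows
cannot inflate any count.

## Co-occurrence and the hypergeometric index

For two same-layer nodes with disease neighbourhoods of sizes $d_a$ and
$d_b$ in a corpus of $N$ diseases, sharing $k$ diseases, the association
score is

$$\mathrm{HyI} = -\log_{10} P(X \ge k), \qquad X \sim
\mathrm{Hypergeom}(N, d_a, d_b).$$

The one-sided enrichment tail makes $\mathrm{HyI} \ge 2$ exactly
"$p \le 0.01$", which is the default significance cut-off for both
phenotype–phenotype and phenotype–gene associations. The tail is computed
in log space (`stats::phyper(log.p = TRUE)`), so scores like HyI ≈ 40 on
strongly co-annotated pairs do not underflow. The upper tail from the
minimal attainable overlap is 1, hence HyI = 0: a pair observed at chance
level carries no signal by construction.

Several definitions of the hypergeometric index circulate in the
co-occurrence literature; the $-\log_{10}$ upper-tail definition above is
the contingency-table-analogous one, and it is deliberately confined to the
single function `hypergeometric_index()` so an alternative convention would
be a one-line change.

## The null universe

The universe $N$ is the number of diseases with complete information
(phenotypes *and* genes) in the analysed corpus, identical for the
bipartite and the tripartite run. This is the one consistent choice: both
neighbourhoods are subsets of exactly that disease set. Nothing else in the
pipeline depends on how the universe was obtained.

## Typical phenotypes

Class-typical phenotypes are extracted by the one-tailed Fisher exact test
on (in/out of class) × (has/lacks phenotype), thresholded at raw
$P \le 0.05$ — the conventional extraction rule for class-typical
phenotypes, which applies no multiple-testing correction at this step.
`typical_phenotypes(adjust = TRUE)` offers a BH-corrected mode for users
who prefer strict error control over convention. Annotations are **not** propagated to
ontology ancestors by default (the true-path rule is not part of the
original procedure); propagation can be studied by pre-expanding the pair
table before `build_corpus()`.

The in-class co-occurrence network keeps pairs whose **both** endpoints are
typical: the network is meant to contain pairs *of* class phenotypes, not
pairs touching one. An `"either"` mode exists on
`restrict_to_typical()`. Scoring all pairs first and filtering afterwards
is order-equivalent for HyI, since each pair's score never depends on other
pairs.

## Over-representation analysis

Each phenotype's HyI-associated gene list is tested against term–gene sets
with the exact hypergeometric tail, BH adjustment, and the usual ORA
parameters: adjusted $p \le 0.05$, $q \le 0.2$, term sizes within
$[10, 500]$ after intersection with the universe. Three choices deserve
explanation:

* **Multiple-testing family** = the terms tested for *one* phenotype's gene
  list, matching how per-gene-list enrichment tools behave — not the global
  phenotype × term grid.
* **q-values** use the BH-based estimate with $\pi_0 = 1$, numerically the
  BH-adjusted p. Tools that refine $\pi_0$ by spline fitting report
  slightly smaller q; with $q \equiv p_{adj}$, the $q \le 0.2$ filter can
  never reject a row that the $p_{adj} \le 0.05$ filter accepts.
* **Universe default** = all genes annotated to at least one term in the
  loaded annotation, overridable. The original parameter list names a
  `universe` without fixing one.

Annotation namespaces (GO biological process, KEGG, Reactome, custom) are
analysed independently — each gets its own `ora()` run and its own BH
family — but pooled when judging cluster coherence.

## Link communities

Communities are communities of *edges*: two adjacent edges (sharing exactly
one endpoint) are similar when the inclusive neighbourhoods
$n^+(x) = \{x\} \cup \mathrm{neighbours}(x)$ of their non-shared endpoints
overlap,

$$S(e_{ik}, e_{jk}) = \frac{|n^+(i) \cap n^+(j)|}{|n^+(i) \cup n^+(j)|},$$

the unweighted default of link clustering for undirected graphs. Edges are
agglomerated by single linkage on $1 - S$ and the dendrogram is cut at the
height maximising the partition density

$$D = \frac{2}{M} \sum_c m_c\,\frac{m_c - n_c + 1}{(n_c - 2)(n_c - 1)},$$

where community $c$ has $m_c$ edges over $n_c$ nodes and a two-node
community contributes 0. Numerical choices:

* **Determinism.** Single-linkage partitions at height $h$ are the
  connected components of the "similarity $\ge 1 - h$" graph over edges, so
  the result does not depend on merge processing order; candidate cuts are
  the distinct merge heights plus the all-singletons cut at 0, and ties in
  density resolve to the **larger** height (fewer, larger communities).
* **Non-adjacent edges** have similarity 0. Adjacent edges always have
  $S > 0$ (the shared endpoint sits in both neighbourhoods), so cuts below
  height 1 never merge edges from different connected components, and every
  community's edge-induced subgraph is connected.
* **Weights.** HyI values are *not* used as edge weights — the unweighted
  Jaccard similarity is the standard default for undirected networks in
  link clustering; a Tanimoto-weighted similarity would slot into
  `edge_similarity()` should a weighted mode be wanted.
* Communities with fewer than `min_nodes = 3` nodes are flagged small but
  never silently removed.

## Functional coherence

A community is coherent when **one** enriched term covers at least 70% of
its member phenotypes (50% as the conventional sensitivity setting). The
denominator is all phenotypes in the community, including those with no
enriched term. The alternative reading — a common *set* of terms — is
stricter and non-monotone in the term list; single-term coverage keeps the
criterion auditable (each shared term lists exactly which phenotypes it
covers) and monotone: raising the threshold can only remove clusters.
Supporting genes are reported per cluster with the fraction of member
phenotypes each gene is associated with, which is what makes pleiotropy
visible as one gene appearing in clusters certified by different functions.

## Null models and validation

* **Prevalence-matched phenotype sets**: "similar prevalence" is
  implemented as decile bins of the candidate disease-count distribution;
  when at most ten distinct counts occur, every count is its own bin, so
  the per-replicate prevalence histogram matches the target bin-for-bin.
  Exhausted bins widen to their neighbours with a warning; targets are
  never resampled.
* **Degree-preserving shuffles** randomise phenotype–function pair lists by
  repeated double edge swaps that reject duplicates, preserving both degree
  sequences exactly; the mixing target is 10 swaps per pair.
* **Empirical p** uses the add-one estimator
  $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n)$ so 100 replicates can
  never report p = 0.
* **Literature co-mention** consumes offline term → PMID indices; the 2×2
  against the recorded corpus size goes through the same one-tailed Fisher
  test as everything else. The total corpus size at query time is an input,
  not a constant.
* **Tissue expression**: a gene is "expressed" when any row of a normal
  tissue table matches a listed tissue (default: cerebellum, cerebral
  cortex, hippocampus, caudate, skeletal muscle, heart muscle) at Medium or
  High level; proportions in two gene sets are compared one-tailed.

# The synthetic world

`generate_corpus()` states a fixed world rather than a tunable one: 200
in-class and 800 out-of-class diseases; 10 phenotype modules of 6, each
tied to a 12-gene function term; in-class diseases draw module phenotypes
with probability 0.9 and module genes with 0.7; every disease draws each of
300 background phenotypes with probability 0.02 and each of 200 background
genes with 0.01. These sizes keep the class a minority (as in real
catalogues), make module phenotypes appear in roughly 18 of their 20 module
diseases (deep in the significant regime, so recovery failures indicate
bugs rather than power), and keep a full pipeline run under a few seconds.
The literature generator mentions every term in each of 10 000 documents
with probability 0.03 and lifts planted within-module pairs' joint mention
10-fold — enough that most planted pairs test significant while independent
pairs stay at the nominal rate.

What the generator does **not** emulate: ontology structure among
phenotypes (no ancestor redundancy), realistic term frequencies, disease
heterogeneity within a module, or phenotypic-series structure. A green
recovery test therefore establishes that the machinery finds the structure
it is pointed at — not that real catalogues contain such structure, nor
that real-data counts would be reproduced.

One global seed fans out to per-stage child seeds
(`child_seed(seed, stage)`), so corpus, literature and control resampling
are independently reproducible; all derived seeds stay below $2^{31}$.

# Degenerate inputs and edge cases

* A single-disease corpus gives every pair tail 1 and HyI 0.
* An empty edge set cannot be clustered (error); a single edge is one
  community with partition density 0.
* Diseases lacking either annotation kind are dropped by `build_corpus()`;
  an empty corpus after filtering is a fatal error carrying the diagnostic
  counts.
* Obsolete ontology terms do not resolve; alternative ids resolve to their
  primary term; dangling `is_a` targets are recorded, not fatal.
* Genes absent from the expression table count as not expressed (with a
  warning), mirroring how incomplete expression atlases are handled in
  practice.

# Known limitations

* The BH-based q-value is conservative relative to spline-$\pi_0$
  estimates.
* Keyword classification matches titles and alternative titles only — not
  clinical-synopsis free text — as the reproducible reading of a database
  keyword search.
* Link clustering stores a dense edge-distance matrix; networks beyond a
  few thousand significant pairs would need a sparse implementation.
* Co-mention matching is exact (case-insensitive) on names and synonyms;
  natural-language variants escape it, which deflates co-mention counts for
  real and shuffled pairs alike.
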