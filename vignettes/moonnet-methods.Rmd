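---
title: "Detecting extreme multifunctional proteins: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting extreme multifunctional proteins: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moonnet)
```

# The problem and the inference principle

A moonlighting protein performs several autonomous, unrelated functions.
In an interactome, such a protein is expected to interact with different
partner sets for each function, so it should lie at the intersection of
several network modules — and, if the functions are truly unrelated, the
modules' biological-process annotations should be *dissimilar*.
`moonnet` operationalizes this as a four-stage screen: overlapping
clustering, majority-rule module annotation, hypergeometric term-pair
dissimilarity, and a dual e-value candidate call. Each stage is an
exported function; `moongo()` chains them and returns a classed object
with `print()`, `summary()`, `plot()` and `simulate()` methods
(`simulate()` runs the randomization controls).

# Overlapping clustering

The clustering must allow overlap, since multifunctionality *is*
multi-module membership. We re-implement the OCG (overlapping cluster
generator) idea with a pinned, fully deterministic contract:

* **Initial system — centered cliques.** For each vertex `v` in
  lexicographic order, a clique is grown from `v` by repeatedly adding
  the neighbour of `v` adjacent to all current members, preferring the
  highest degree and breaking ties lexicographically. Duplicates and
  cliques contained in others are removed. Isolated vertices become
  singletons.
* **Merging.** The pair of clusters sharing a node or joined by an edge
  whose union maximally increases the overlap modularity is merged;
  merging stops when no gain is strictly positive. Ties are broken on
  the lexicographically smallest pair of cluster fingerprints.
* **Modularity.** `Q = (1/2m) * sum [A_uv - d_u d_v / (2m)]` over
  ordered node pairs that share at least one cluster, the diagonal
  included, each pair counted once however many clusters it shares.
  With this convention a single whole-graph cluster scores exactly 0
  and a disjoint partition reduces to classical Newman modularity,
  which is what the brute-force oracles in the test suite check.

Because a merge only ever adds covered pairs, the accepted-merge gain
equals the modularity difference, so `Q` is non-decreasing along the
merge sequence by construction. Merges across connected components are
never accepted (their gain is a pure null-model penalty), so components
are clustered independently. The implementation keeps dense per-node
bookkeeping and quadratic cluster-pair scans: it is written for
module-scale graphs (up to a few thousand nodes), not for repeated
clustering of very large interactomes.

This is a re-implementation from a pinned specification, not a
byte-level port of the original OCG binary; cluster-for-cluster
equivalence with historical class files is a soft benchmark only.

# Module annotation

A cluster is annotated to every biological-process term carried, in the
propagated view, by at least `threshold` (default 0.5, compared with
`>=`) of its *annotated* members; unannotated members do not dilute the
denominator. Propagation follows the GO true path over `is_a` and
`part_of` only — regulates-type relations are not propagated, a choice
made explicit because different GO toolchains disagree here. The
ontology root is never assignable: clusters whose members agree only at
the root are "BP unknown" (an empty term set in the class file).

Qualifying terms are reduced to the most specific ones, because the
propagated closure otherwise always co-assigns every ancestor of any
qualifying term. Raising the threshold can only remove qualifying terms,
a monotonicity the tests assert. A depth cap below the most-specific
reduction is deliberately *not* applied by default: with shallow
corpora it is a no-op, and with deep ones the most-specific rule already
tracks the data.

# Term-pair association probabilities

Two hypergeometric measures ask how often a pair of terms co-occurs:

* **Annotation probability.** Counted on proteins with at least two
  distinct *direct* annotations: `N` such proteins, `K` directly
  annotated to GO1, `n` to GO2, `k` to both; the dissimilarity measure
  is the lower tail `P(X <= k)`.
* **Interaction probability.** The same form on edges whose endpoints
  both lie in that two-annotation universe: `K` edges touching a GO1
  protein, `n` touching a GO2 protein, `k` edges with one endpoint on
  each side. An edge whose single endpoint carries both terms is not a
  cross pair — which also means the observed `k` may legitimately fall
  below the classical support `max(0, K + n - N)`; the lower tail is
  then simply 0.

The lower tail is used for dissimilarity because the screen asks whether
two processes are *rarely* performed by one protein or by interacting
proteins; the upper tail is exposed for similarity queries. Direct
(unpropagated) annotations are counted, so that the ubiquitous shared
ancestors of the propagated view do not mask rarity.

Correction is Bonferroni-style by design: `e = p * n_tests`, with
`n_tests` the number of term pairs actually evaluated at run time (pairs
with a zero margin in either view are skipped and excluded from the
count; e-values are capped at 1 for reporting). A pair is dissimilar iff
**both** e-values are at or below `alpha` (default 0.05).

**Small-network behaviour.** The interaction statistic has a structural
bias worth knowing about: for two disjoint label sets, "touches GO1" and
"touches GO2" are negatively associated across edges (an edge with both
endpoints in GO1 cannot touch GO2), so on small dense graphs the lower
tail can look significant under pure random mixing. On sparse,
large-universe data — where each term covers a small fraction of
proteins — the effect is negligible, but it shapes what the synthetic
null controls can show at fixture scale (below).

# Candidate calling

For every protein in at least two non-"BP unknown" clusters, every
cross pair of the clusters' assigned terms (a term never pairs with
itself) is looked up in the pair table; evidence is recorded whenever
both e-values pass. Evidence is exhaustive, which supports the
provenance classification: a candidate either already carried both
terms of its best evidence pair, carried one and inherited the other,
or inherited both from its modules. Candidates are by construction a
subset of multiclustered proteins, and lowering `alpha` can only shrink
the set — both are asserted as properties in the tests.

# Randomization controls and validation

`simulate()` re-runs detection under four null schemes, each conserving
an exact invariant (asserted in the tests):

* `annotation_shuffle` — per-protein direct-annotation *sets* permuted
  across proteins (conserves the multiset of sets), clusters
  re-annotated on the observed topology;
* `edge_uniform` — a fresh G(n, m) graph on the same nodes and edge
  count, full pipeline re-run;
* `edge_degree_preserving` — double-edge swaps (10 attempted swaps per
  edge, a standard mixing heuristic; the degree sequence is conserved
  exactly), full pipeline re-run;
* `probability_shuffle` — the (p_annot, p_inter) tuples permuted across
  term pairs, e-values recomputed, detection re-run.

Leave-one-out recovery masks one protein's annotations, re-annotates
its cluster and scores whether any held-out propagated term reappears
among the inferred terms or their ancestors. Known-set enrichment
reports the fold over expectation and the one-sided upper-tail
hypergeometric probability; the point probability of the observed
overlap is exposed alongside, since published analyses sometimes report
that quantity. On the published interactome counts (12,865 proteins,
430 candidates, 39 curated moonlighting proteins, 6 recovered) the
package computes a 4.6-fold enrichment with an upper tail of 1.7e-3 and
a point probability of 1.5e-3.

# The synthetic scenario generator

`generate_scenario()` builds the study conditions every stage is tested
under. It emulates, at fixture scale, the features of real data the
method relies on:

* **Planted modules as dense blocks.** Intra-module edges with `p_in`
  (default 1.0), inter-module noise with `p_out` (default 0.01); 8
  modules by default.
* **Study-biased annotation density.** Two *focal* modules (sizes 20)
  are richly annotated: each member carries its module's term plus a
  private rare term, so focal proteins form the two-annotation universe
  of the pair probabilities — mirroring real corpora, where annotation
  depth concentrates on well-studied processes and most terms annotate
  very few proteins. The six background modules (sizes 10) carry their
  specific term only.
* **One branch per process.** Each module term sits in its own branch
  under the root, so distinct processes share no ancestry below the
  root. This term diversity is what makes randomized topologies behave
  as on real data: arbitrary protein groups share no majority term and
  fall to "BP unknown".
* **Planted EMFs.** `n_shared_nodes` (default 2) extra nodes are
  members of both focal modules but directly annotated to only one
  side's term — the second function is precisely what module
  inheritance reveals, and their sparse annotation keeps their bridging
  edges out of the interaction universe, as for a protein whose second
  role is not yet curated.
* **Annotation noise.** Exclusive members are annotated to their own
  module's term with probability `annotation_purity` (default 0.9),
  otherwise to a uniformly drawn other module's term.

All randomness flows through the `seed` argument; no global RNG state
is touched. Under the defaults, across seeded replicates: with
`p_out = 0` the pipeline returns exactly the planted EMFs with perfect
module recovery; with noise the planted EMFs remain a subset of the
candidates and best-match Jaccard recovery stays above 0.9 (extra calls
are proteins that genuinely satisfy the rule through small
boundary-overlap clusters — a property of overlap clustering at module
boundaries, not a bookkeeping error). Leave-one-out recovery increases
with `annotation_purity`.

**What fixture-scale nulls can and cannot show.** Annotation shuffling
collapses both annotated-cluster counts and candidates; uniform edge
randomization and probability reshuffling collapse candidates toward
zero. The degree-preserving null is different: on a ~100-node fixture
where the planted bridges hold a visible share of total degree,
rewired graphs regenerate cluster-spanning hubs at a rate that can
*exceed* the planted scenario's own candidate count. This is the
fixture-scale expression of a real phenomenon — degree-preserving
rewiring is by far the weakest of the three topology controls at full
scale too — so the tests assert the directional collapse for the other
three schemes and the exact degree-sequence conservation for this one,
and the acceptance report states its mean as computed.

# Numerical and interface choices

* Tie-breaking is lexicographic everywhere (clique growth, merge
  selection, output sorting), making every stage deterministic given
  its inputs; identical runs produce byte-identical output files.
* Probabilities come from `stats::phyper`/`dhyper`; rank-sum
  comparisons from `stats::wilcox.test` (exact for small tie-free
  samples); graph containers and standard graph algorithms (degree,
  Brandes betweenness, geodesics, G(n, m) sampling, degree-preserving
  rewiring) from `igraph`. Betweenness is unnormalized over unordered
  pairs with endpoints excluded; on a 4-cycle every vertex scores 0.5.
* Degenerate inputs have defined behaviour: empty edge lists, clusters
  of entirely unannotated proteins, term pairs with empty margins,
  unreachable node pairs in path summaries, and candidate sets that are
  empty all take documented paths (error or sentinel, never silence).
* The hub rule defaults to `ceiling(2 * mean(degree))` and accepts an
  absolute override, since published analyses typically fix a round
  threshold.
* No multiple-testing correction is applied across the many signature
  comparisons in the characterization step; p-values there are reported
  raw, and the documentation says so.
* Problem sizes in the test suite and acceptance script (modules of
  10–20 nodes, ~100-node networks, 10 seeds, 10 null replicates) were
  chosen so the whole battery exercises every stage — including
  repeated re-clustering under nulls — at interactive speed.

# Known limitations

* The OCG re-implementation targets module-scale graphs; clustering a
  12,000-node interactome works but is slow, and the merge contract is
  a pinned specification rather than a byte-level reproduction of the
  original binary.
* The interaction probability's small-universe bias (above) means
  dissimilarity calls on networks of a few hundred edges should be
  treated cautiously; the statistic is designed for corpora where each
  term covers a small fraction of a large edge universe.
* Identifier semantics are the caller's responsibility: IDs are opaque
  case-sensitive strings, and no isoform or cross-database mapping is
  attempted.
* Sequence- and structure-level candidate features (disorder, motifs,
  domains, conservation, expression breadth) are ingested from
  user-supplied tables and never computed.
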