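---
title: "Meta-hub gene discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-hub gene discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metahubr)
```

`metahubr` turns a cross-disease hub-gene study into a reproducible
pipeline: intersect per-disease gene lists, rank the shared signature's
interactome by eleven topological measures, detect dense complexes, build a
consensus hub list, enrich it, prioritize candidates through seven signals,
and superimpose directed disease maps to expose the shared signalling core.
This vignette explains the models behind each stage, the parameters that
matter, the numerical conventions, and what the synthetic-data tests do and
do not establish.

## Gene lists and the Venn core

Gene symbols are normalized by uppercasing and whitespace stripping only.
No alias or HGNC resolution is attempted: literature-mined lists mix
synonyms in ways no offline heuristic resolves safely, so identifier
mapping is deliberately left upstream of the package.

Lists keep duplicate occurrences in sequence — an occurrence count is how
often independent articles nominated a gene, and becomes prioritization
parameter 1 — but every set operation (`intersect_all()`, Venn regions,
annotation overlap) uses distinct symbols. Venn regions are *exclusive*
(keyed by the exact label subset), so they partition the union; this is
asserted as a property test on random collections.

## The interactome

`read_network()` accepts STRING-export-style TSVs: at least three columns
(node1, node2, combined score), header auto-detected, scores either on the
0–1 scale or STRING's 0–1000 integers (rescaled when any score exceeds 1).
Three conventions, chosen where the format is silent:

* duplicate pairs collapse keeping the **maximum** score (the most
  confident evidence wins);
* self-loops are dropped with a warning — every downstream measure assumes
  a simple graph;
* the default threshold `min_score = 0.4` is the conventional
  medium-confidence STRING cutoff.

Average degree is `2|E|/|V|` and density `2|E|/(|V|(|V|−1))`; both are 0
for degenerate vertex sets rather than `NaN`.

## The eleven hub measures

The measures follow the conventions popularized by the CytoHubba family of
hub detectors. They are defined in `?compute_measure`; the choices worth
justifying:

* **Closeness** is *harmonic* (`Σ 1/d`), not classical, so disconnected
  graphs score sensibly (unreachable vertices contribute 0).
* **EcCentricity** is reported inverted (`1/max d` within the component) so
  that, like every other measure, larger means more central; an isolated
  vertex scores 0.
* **Radiality** uses the diameter of the vertex's own component and
  normalizes by `|V|−1` over the whole graph, which keeps cross-component
  scores comparable.
* **BottleNeck** depends on a BFS shortest-path tree, which is not unique;
  parent ties are broken by the lexicographically smallest parent symbol,
  making the measure deterministic. A root `s` counts towards `v` when
  strictly more than `bottleneck_fraction` (default 1/4) of `s`'s tree
  routes through `v`.
* **DMNC** uses exponent ε = 1.7 and, when neighbourhood components tie in
  size, takes the one with more edges (then smallest member symbol).
* **MCC** falls back to the degree when no two neighbours are adjacent
  (otherwise the `(|C|−1)!` clique sum is used as-is).
* **EPC** is the only stochastic measure: each edge is kept independently
  with probability `epc_retention` (default 0.5; `"edge-weight"` uses each
  edge's confidence), and a vertex scores the mean size of its surviving
  component over `epc_realizations` (default 100) seeded realizations.
  Retention 1 recovers the component size exactly — the hook the
  brute-force equivalence tests use, since a seed-matched re-run would not
  be an independent check.

Ranks are assigned per measure by score descending, ties by symbol
ascending, so a rank table is a permutation of `1..|V|` per measure and
fully reproducible given the seed. The ranking tie policy is the package's
own convention; published analyses rarely state theirs.

All measures treat the graph as unweighted (EPC's edge-weight mode aside):
the upstream analyses this mirrors are threshold-then-topology pipelines,
not weighted-shortest-path ones.

## MCODE-style complex detection

Vertex weight: for each vertex with degree ≥ `degree_cutoff` (default 2),
take the subgraph induced on the **open** neighbourhood `N(v)`, find its
highest k-core, and set `weight = k × density(core)`. The open
neighbourhood is this package's normative contract (on `K5` every weight is
`3 × 1 = 3`); implementations differ on whether `v` itself is included, so
the convention is pinned here and verified against an independent
iterative-deletion k-core oracle.

Growth: from the highest-weight unassigned vertex, neighbours join while
their weight is at least `(1 − VWP) × seed weight` (`node_score_cutoff`,
default 0.2), breadth-first to `max_depth`. Post-processing: *haircut*
(default on) trims the cluster to its 2-core, so no member has
within-cluster degree 1; *fluff* (default off) adds boundary vertices whose
closed-neighbourhood density exceeds `fluff_density`, and is the only way a
vertex can appear in two clusters (flagged in the tidy output). Clusters
whose subgraph has no `k_core_filter`-core (default 2) are discarded; their
vertices remain available to later seeds. Both the haircut and no-haircut
paths are exercised in tests, as is fluff, because "default settings" in
published analyses underdetermines them.

One edge case surfaced by the property tests: the haircut can trim the very
vertex growth started from. The emitted cluster then reports its heaviest
remaining member as seed, keeping the invariant that the seed belongs to
the cluster.

Cluster score is `density × size`, recomputed independently in tests for
every emitted cluster.

## Enrichment, BH and kappa grouping

Over-representation uses the one-sided hypergeometric tail (the Fisher
exact test for a 2×2 table with fixed margins), computed by
`stats::phyper` and cross-checked against exhaustive tail summation for
every configuration with universe ≤ 15. When no universe is supplied the
union of all collection members is used — **this default changes
p-values**, and analysts with a defined background (e.g. all assayed genes)
should always pass it explicitly.

Benjamini–Hochberg adjustment is delegated to `stats::p.adjust` behind
`bh_adjust()`, which adds domain validation and order-preservation
guarantees (tested against hand-computed step-up vectors).

Redundant terms are grouped ClueGO-style: each significant term becomes a
binary membership vector over the *query* genes, pairs with Cohen's
κ ≥ `kappa_threshold` (default 0.4, configurable — published analyses
report group counts, not thresholds) are single-linkage merged, and each
group is represented by its most significant member. Identical vectors get
κ = 1 by convention even when expected agreement is 1.

## Consensus, merging and prioritization

Consensus "frequency" is membership count in the per-measure top-`k`
(default 10) lists, over **all eleven** measures — the natural reading of
frequency-of-occurrence aggregation; a "significant majority of methods"
variant would only reweight ties and is not implemented. Ties break by mean
rank over contributing measures, then symbol. `merge_hub_cluster()` keeps
hub-list order, appends novel cluster genes, and asserts
`|union| = |A| + |B| − |overlap|`.

The seven-parameter ledger selects: the single best performer for
redundancy (1), consensus rank (2), cluster-weight rank (3) and
enrichment frequency (5), ties by symbol; every member of the hub∩cluster
overlap (4); and every gene whose expression direction is identical — and
not `unknown` — across **all** configured diseases, separately for
database (6) and literature (7) annotations. `unknown` disqualifies: that
is the strictest reading of "common expression pattern", chosen so missing
data can never create a concordance call. A parameter with no positive
signal (e.g. all redundancy zero) selects nobody rather than an arbitrary
gene. The shortlist is the union with per-gene provenance; removing a
parameter can only shrink it.

## Disease maps and the core equation

Maps are directed edges `(source, target, effect, disease)` with effects in
{activate, inhibit, regulate}; self-edges are rejected. Superimposition
keeps a `(source, target)` pair present in at least `min_support` diseases
(default: all), collapsing conflicting effects to `regulate` with a
warning. At `min_support = 1` this is the edge-set union and at full
support the intersection — both asserted against set-algebra oracles.

The *hub of hubs* maximizes `|ancestors ∪ descendants|` — directed
reachability both ways, not just direct edges. Reachability is the chosen
reading of "within the signalling stream": on the shipped three-disease
core map it makes AKT1 the hub with connectivity 6 (all nodes except
CTNNB1 and the isolated IFNG), which direct-neighbour counting would not
reproduce. The core equation is then the hub's direct in- and
out-neighbours: `EGFR,CD44 ⇒ AKT1 ⇒ NFKB1+STAT3+MMP9`, six nodes.

The shipped fixture pins one concrete reading of an ambiguity in how the
downstream matrix-metalloproteinase edges wire (whether NFKB1 or STAT3
feeds MMP1 vs MMP9); a dedicated test swaps the wiring and shows the hub
identity, the six-node equation and the eight-of-nine participation count
are invariant to that choice.

## The synthetic-data generators

`synthetic_spec()` fixes the simulated study conditions; all generators are
pure functions of it (byte-identical outputs per seed, asserted):

* **Gene lists** — three lists of 376, 567 and 360 genes over a
  2000-symbol universe sharing a planted 31-gene core, the scale of the
  motivating text-mining corpus. A repair pass guarantees no non-core gene
  lands in every list, so the Venn core is exactly recoverable. (A much
  smaller universe is infeasible here: three lists of those sizes over
  500 genes would be forced by counting alone to share hundreds of genes.)
  Duplicate occurrences are injected at rate 0.1 to exercise the
  redundancy signal.
* **Network** — a planted module of 8 vertices wired at `p_in` inside a
  40-vertex background wired at `p_out` (0.05 by default: sparse enough
  that background vertex weights stay well under the module's), scores
  uniform on (0.4, 1) so default thresholding is non-trivial but lossless.
  An optional hub vertex wired to every node gives strict maxima for the
  consensus property tests.
* **Gene sets** — 5 planted terms containing 80 % of the query inside
  40-gene terms, plus 20 uniform decoys. Planted terms are detected at
  q < 0.05 with astronomical margin; decoys are null, so their
  significance rate stays at the FDR level. Note the limit this implies:
  with BH at q < 0.05 and several near-zero planted p-values, occasional
  decoy false positives are *expected* (that is what FDR control means),
  so recovery is asserted as "all planted significant, pooled decoy rate
  ≤ 5 %", not as exact set equality.
* **Expression annotations** — a designated concordant subset; every other
  gene is forced discordant or unknown somewhere, so the concordant set is
  exactly recoverable.
* **Disease maps** — a shared core of 9 directed edges in all three maps
  plus 6 per-disease noise edges drawn from disjoint pair pools, so
  full-support superimposition returns exactly the core.

What passing these tests shows: the algorithms recover planted structure
under the stated conditions, deterministically, and agree with independent
brute-force implementations on small graphs. What they do not show:
robustness to the things real data adds — scale-free degree structure,
symbol aliasing, correlated annotation errors, literature bias in mined
lists. The generators emulate none of those by design (uniform sampling
throughout); conclusions about real cohorts still require the usual
sensitivity analysis.

## Numerical and scale choices

Problem sizes in the test suite are chosen to keep the default run around a
minute: oracle equivalence runs on every labelled connected graph on ≤ 4
vertices, a deterministic ninth of the 728 labelled connected 5-vertex
graphs, and 50 seeded random graphs on 6–8 vertices; the EPC analytic check
uses 2×10⁴ realizations against a 3σ band; recovery experiments use 20
seeds. All randomness flows from explicit integer seeds, and the pipeline
manifest records every parameter (including defaults) plus MD5 digests of
every input, so "default settings" is always auditable after the fact.

## Known limitations

* No identifier mapping; symbol hygiene is the caller's responsibility.
* All measures unweighted except EPC's edge-weight mode; no weighted
  shortest paths.
* One-sided over-representation only; depletion is out of scope.
* The kappa grouping is single-linkage and can chain; at large term counts
  a stricter linkage may be preferable.
* Exact reproduction of any published cluster or edge count depends on the
  exact interactome export behind it; version-dependent edge sets are
  treated as inputs, never as test oracles.
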