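---
title: "Directed reaction-centric graphs: metrics, cascades and null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed reaction-centric graphs: metrics, cascades and null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reacgraph)
```

## The representation

A metabolic network is a set of reactions transforming metabolites. Most
topological work represents it metabolite-centrically; `reacgraph` uses the
reaction-centric view instead, because reaction nodes map one-to-one onto
gene deletions and flux-balance essentiality calls. The graph is directed
and simple: node set = reactions, arc `u -> v` whenever some metabolite
producible by `u` is consumable by `v`, annotated with the mediating
metabolite set, with self-arcs and parallel arcs forbidden.

Reversible reactions are kept as single nodes with direction-union
semantics: `producible(r) = products ∪ (substrates if reversible)` and
symmetrically for consumables. The canonical three-step example — ASAD
(4pasp ↔ aspsa), HSDy (aspsa ↔ hom-L), HSK (hom-L → phom) — therefore
yields exactly `ASAD ↔ HSDy → HSK`, a 2-cycle plus one arc, which is what
`build_reaction_graph(example_asad_model())` returns. The alternative of
splitting reversible reactions into forward/backward nodes would double the
node count and break that correspondence, so it was rejected.

### Filtering

Three filters run before arcs are formed:

1. **Exchange reactions** (a side of the equation empty, or an id prefixed
   `EX_`/`DM_`/`SK_`) are boundary pseudo-reactions, removed by default.
2. **Transport reactions** (identical compartment-stripped species
   multisets on both sides, with at least one compartment change) shuttle
   material across membranes without transforming it, removed by default.
3. **Currency metabolites** (ATP, NAD(P)(H), water, protons, phosphate,
   CO2, ...) are struck from every reaction; paths routed through them are
   biologically meaningless shortcuts. The literature names only examples,
   never a complete list, so the default in
   `default_currency_metabolites()` (25 base ids) is an explicit package
   choice, versioned here and overridable via `filter_config()` or a
   YAML/JSON config file. **Node and arc counts of converted genome-scale
   models depend on this list**; counts published elsewhere are
   reproducible only up to the currency list and model release used there.

Reactions left with no metabolites are dropped; reactions left isolated
remain nodes (they legitimately carry cascade number 0 and degree 0).

## Centrality metrics

For node `i`, let `Λ(i)` be the union of in- and out-neighbors (`i`
excluded; a mutual neighbor counted once), `k_i = |Λ(i)|`.

- **Clustering** `C(i) = n_i / (k_i (k_i − 1))` with `n_i` the number of
  directed arcs among `Λ(i)`. The denominator counts ordered pairs, so
  `C ∈ [0, 1]` with 1 on a complete bidirectional digraph. For `k_i ≤ 1`
  the ratio is 0/0; the package defaults to 0 (`singleton = "zero"`), with
  `"one"` available because both conventions appear in the literature and
  published single-neighbor cells are not decodable unambiguously.
- **Betweenness** `B(i) = Σ σ_jk(i)/σ_jk` over ordered pairs with
  `σ_jk > 0`, directed, unweighted, *unnormalized* — published per-node
  values are integer-scale path counts, which only the unnormalized form
  reproduces. Computation uses Brandes' algorithm via igraph; the test
  suite checks it against an independent simple-path enumerator.
- **Bridging coefficient**
  `BC(i) = degree_total(i)⁻¹ / Σ_{j∈Λ(i)} degree_total(j)⁻¹`, gated to 0
  when `degree_in(i) = 0` or `degree_out(i) = 0`: in a directed network a
  node without through-flow cannot carry information between its
  neighbors. The ungated (classical, undirected-style) value is exposed as
  `gated = FALSE` because published node tables report the ungated value
  for pure sources while using the gate inside bridging centrality — the
  two conventions only differ on nodes with `B(i) = 0`, where the product
  is unaffected. Both variants are first-class and tested.
- **Bridging centrality** `BrC(i) = B(i) × BC(i)` (gated form), large for
  low-degree nodes with high-degree neighbors sitting on many shortest
  paths — bridges between modules, empirically enriched for cofactor and
  prosthetic-group biosynthesis reactions in microbial models.

## The cascade algorithm

The cascade set formalizes "what shuts down if this reaction stops". A
failed node starves a downstream node when *all* of that node's
in-neighbors have failed; starvation propagates to a fixpoint:

```
F <- {seed}
repeat until stable:
  add any u ∉ F with in-degree(u) > 0 whose every in-neighbor is in F
cascade_set(seed) = F \ {seed}
```

Nodes with in-degree 0 are self-supplied and never starve; nodes inside a
directed cycle survive while any arc into the cycle is live (in the
worked-example graph, removing E does not kill F because G keeps feeding
it). The fixpoint is order-independent, hence deterministic. The
implementation maintains a live-in-neighbor counter per node and a
worklist, O(|V| + |A|) per seed and O(|V|(|V| + |A|)) for `all_cascades()`;
an independently coded delete-and-strip oracle confirms it on hundreds of
random digraphs.

Properties the suite asserts rather than assumes: absorption (if
`v ∈ cascade(w)` then `cascade(v) ⊆ cascade(w)`, up to `w` itself in the
mutual-membership corner), and the leading-node rule (a node is *leading*
iff it appears in no other cascade set). Mutual membership — two nodes each
in the other's set, possible only when their sets coincide — is reported as
non-independent for both, with a warning; realistic metabolic graphs have
not exhibited it.

Cascade subnetworks (seed plus cascade set, induced arcs only) classify as
`linear_path`, `tree` (arborescence from the seed), or `other`; the
classification deliberately looks at induced arcs, not full ancestry,
because the types describe the failed region itself.

## Global topology

- **Degree distributions** report `P(k)` over all nodes including `k = 0`;
  power-law fits exclude `k = 0`.
- **Power-law exponents** default to least squares on `log P(k)` vs
  `log k`. Exponent magnitudes near 1.3–1.5 reported for reaction graphs
  are characteristic of this estimator on raw distributions; a
  continuous-approximation MLE (`k_min = 1`) is included as a diagnostic.
  The log-log fit recovers exact synthetic exponents to ±0.02 (asserted in
  the tests for γ ∈ {−1.3, −1.5, −2.0}).
- **Directed modularity**
  `Q = (1/m) Σ_{c(u)=c(v)} [A_uv − k_u^out k_v^in / m]`. Community
  detection is a deterministic greedy agglomeration on directed Q (merge
  the connected community pair with the largest gain until none is
  positive), optionally refined by seeded local node moves
  (`method = "move"`). No installed R routine optimizes the directed form,
  so the optimizer is implemented here and cross-checked against an
  independent arc-counting evaluation of Q. Any published absolute Q value
  is optimizer-dependent and treated as indicative, not as a target.
- **Null model**: degree-preserving double-arc swaps (igraph's
  `keeping_degseq`, default `10 × |A|` attempts, self/parallel arcs
  rejected), 100+ replicates, detection re-run per replicate, and the
  add-one empirical p `(1 + #{Q_null ≥ Q_obs})/(1 + R)` — never exactly
  zero by construction, so a report of "p = 0" corresponds here to
  `p = 1/(R + 1)`. The degree sequence of every replicate is hard-checked.

## Essentiality enrichment

Flux-balance reaction-deletion simulation (external to this package — any
constraint-based toolbox produces it) yields a binary essential label per
reaction; `read_essentiality_labels()` ingests the TSV. Enrichment
summaries: top-fraction proportions with an upper-tail hypergeometric
p-value (`n_top = round(fraction · |V|)` by default, with an explicit
`n_top` override because published tables appear to floor), rank- or
value-binned essentiality percentages, and essentiality of leading cascade
reactions by cascade number (bins 0–6, ≥7 pooled at its minimum, Pearson r
over non-empty bins). Published percentage tables truncate to one decimal
(29/62 prints as 46.7%); comparisons in the tests truncate the same way.
The hypergeometric choice for the tail probability is this package's; the
p-values printed alongside published enrichment tables are of the same
order but evidently from an unnamed, different test, and are not asserted
equal.

## Synthetic data

The generators define the test conditions:

- `fig1_toy_graph()` — the fixed seven-node network whose full metric
  table is hand-verified; it gates the rest of the suite.
- `synthetic_model()` — bipartite stoichiometry over `n_metabolites`
  cytosolic species, 1–3 substrates and products per reaction, currency
  metabolites attached to ~80% of internal reactions, 30% reversible by
  default, and `round(fraction × n)` transport/exchange reactions built to
  the classifier's definitions. Defaults (40 metabolites, 60 reactions,
  10% transport, 10% exchange) are desk-scale stand-ins for genome-scale
  structure: they exercise every conversion rule but do not emulate
  biochemical realism (no mass balance, no flux consistency, no modular
  pathway anatomy), so passing conversion tests demonstrates correctness
  of the rules, not biological fidelity.
- `random_digraph()` — Erdős–Rényi digraphs for property tests;
  `planted_two_clique_graph()` — two bidirectional k-cliques joined by one
  arc, the canonical modular graph for null-model tests.

All generators restore the global RNG state and are deterministic given
`seed`.

## Numerical and scale choices

Tests and the acceptance script run at deliberately small sizes — toy
graph, digraphs up to n = 50 for cascades and n = 8 for path-enumeration
oracles, 100 null replicates on a 10-node planted graph — chosen so the
whole suite completes in well under a minute while still exercising every
code path; the genome-scale pipeline (≈1250 nodes, ≈9000 arcs) runs the
same code and completes in seconds for metrics and minutes for a
1000-replicate null test. Ties everywhere (top-k cutoffs, community
merges, output files) break lexicographically by node id so outputs are
byte-stable. Degenerate inputs have defined behavior: empty graphs give
empty tables, an empty currency list warns and filters nothing, graphs
with fewer than two arcs cannot be rewired and return a copy with a
warning, and modularity of an arc-less graph is undefined (error).

## Limitations

- Arc formation is presence/absence; stoichiometric coefficients are
  stored but unused (no flux weighting).
- Exact node/arc counts for converted public models are
  configuration-sensitive (currency list, boundary prefixes, model
  release); only per-reaction quantities (degrees of named reactions,
  cascade sets of named seeds) are robust across reasonable
  configurations.
- The cascade algorithm propagates downstream starvation only; upstream
  product-loss propagation (as in bidirectional topological flux-balance
  failure analyses of bipartite graphs) is out of scope.
- SBML support covers the BiGG-style L2/L3+fbc subset (species, reactions,
  stoichiometry, reversibility, flux bounds), not kinetics or SBML
  writing.
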