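---
title: "Target identification for multi-herb formulas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target identification for multi-herb formulas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

A multi-herb formula contains hundreds of chemicals, most of which
never reach systemic circulation or bind nothing of interest. The
question this package answers is: *given what is known about the
compounds, the disease, and the protein interactome, which proteins
are the plausible therapeutic targets of the formula?* The pipeline
combines pharmacokinetic pre-screening, bipartite network
construction, interactome intersection, a topological hub filter, and
gene-set enrichment. Each stage is an exported function; `run_pipeline()`
chains them.

## Compound screening

Oral bioavailability (OB, percent of an oral dose reaching
circulation) and drug-likeness (DL, a unitless 0–1 structural
similarity to approved drugs) arrive as columns of the compound table;
computing them from structure is out of scope. The screen keeps a
compound when

* OB ≥ 30 % **and** DL ≥ 0.18 (reason `threshold`),
* or DL is absent and OB ≥ 35 % (reason `no_dl_rule`),
* or its id is whitelisted (reason `rescued`).

Both comparisons are inclusive (≥): the thresholds follow the TCMSP
screening convention, which states them as minima. The no-DL fallback
is implemented as a general rule with a configurable threshold rather
than a special case for particular compounds, because a rule keyed to
named compounds would not transfer to other formulas. Rescue is
id-based: published rescues are justified narratively, compound by
compound, so a whitelist file is the only faithful mechanism. A record
with neither OB nor DL is excluded (with a warning) unless
whitelisted — there is no basis to keep it.

## Networks

The compound–target map induces a bipartite graph whose two node sets
are namespaced (`cpd:`, `tgt:`) so identifiers can never collide.
Compounds without any mapped target are excluded from the graph but
reported. Because published node counts for such networks sometimes
count a shared compound once per herb, `bipartite_stats()` reports
both conventions (`n_nodes` and `n_nodes_herb_expanded`).

Gene symbols are normalized by uppercasing and trimming only. No alias
mapping is attempted: identifier reconciliation schemes differ between
databases, and a wrong merge is worse than a missed one. The
normalization is idempotent and applied at every file boundary.

Seed expansion uses one-hop neighborhoods: the network for a seed set
is the subgraph induced on the seeds plus their direct interactors,
matching the default behaviour of interactome-assembly tools that "add
nodes and their interactors". Isolated seeds are dropped and reported.
Network intersection is node-wise and edge-wise; when both inputs are
induced subgraphs of one parent PPI — which is always the case inside
this pipeline — edge-set intersection coincides with the induced
subgraph on the common nodes.

## The six centrality measures

On the simple undirected graph with adjacency matrix $A$:

* **DC** — degree.
* **BC** — betweenness, as unnormalized path-pair counts:
  $\sum_{s<t,\,s,t\neq v} \sigma_{st}(v)/\sigma_{st}$, each unordered
  pair counted once, cross-component pairs contributing zero.
* **CC** — closeness within the node's component:
  $(n_c-1)/\sum_u d(v,u)$; isolated nodes get 0.
* **EC** — the node's entry of the nonnegative principal eigenvector
  of its component's adjacency matrix, each component's vector scaled
  to unit Euclidean norm. Computed by power iteration from the
  all-ones vector on $A+I$: the shift leaves the eigenvectors
  unchanged, but makes the principal eigenvalue strictly dominant so
  the iteration also converges on bipartite components, where
  iterating on $A$ itself oscillates with period two. Tolerance
  `1e-12`, at most `1e5` iterations, sign fixed nonnegative.
* **NC** — the sum over incident edges of the edge clustering
  coefficient $\mathrm{ECC}(u,v) = z(u,v)/\min(d_u-1, d_v-1)$, where
  $z$ counts triangles containing the edge; a degree-1 endpoint makes
  the denominator zero and the contribution is defined as 0 (such an
  edge cannot close a triangle).
* **LAC** — the mean degree of $v$'s neighbors within the subgraph
  induced on those neighbors (equivalently $2t(v)/d_v$ with $t(v)$
  the triangle count at $v$); 0 for isolated nodes.

Degree, betweenness and closeness delegate to igraph; EC, NC and LAC
are implemented here because no installed package provides these
variants. The test suite checks all six against an independent
brute-force oracle (distances and shortest-path counts from adjacency
powers, eigenvectors from `eigen()`, triangles from triple loops) on
hundreds of random graphs at tolerance `1e-8`, plus exact closed forms
on stars, paths, cycles and cliques.

## The two-stage filter

Stage 1 keeps nodes with degree strictly greater than twice the median
degree; stage 2 recomputes all six measures **on the induced
significant subgraph** and keeps nodes strictly above all six medians
simultaneously. Both inequalities are strict ("more than twice",
"greater than the median"), so on a vertex-transitive graph — where
every node attains every median — the result is empty; the tests pin
this behaviour on cycles, complete graphs and toroidal lattices.
Recomputing on the induced subgraph (rather than inheriting
parent-network values) matters: the significant subgraph is much
denser than its parent, and published stage-2 degree medians exceed
the stage-1 cut, which is only possible under recomputation. Medians
use the standard mean-of-middle-two convention for even counts, and
the convention is recorded in the thresholds output for audit.

## Enrichment and term grouping

The enrichment p-value is the exact upper hypergeometric tail,
delegated to `phyper`; tests verify it against explicit
`choose()`-ratio enumeration for every configuration with universe
size up to 25 (tolerance `1e-12`). Benjamini–Hochberg correction is
applied within each term category separately, because the two
categories (molecular function / biological process vs signaling
pathway) are reported as separate families; pooling is a
configuration option. The default universe is the genes appearing in
the gene-set collection intersected with the analyzed network's
nodes. This is the largest genuinely open choice in the pipeline —
annotation tools rarely document their universe — so it is
configurable and logged in the report.

Enriched terms are grouped by Cohen's kappa over binary gene
memberships on a reference set (the universe by default):
$\kappa = (p_o - p_e)/(1 - p_e)$ from the 2×2 agreement table,
defined as 1 when $p_e = 1$. Pairs with κ ≥ 0.4 (the documented
default of the standard grouping tool) are linked; groups are
connected components; the smallest adjusted p-value leads a group,
ties broken by lexicographic term id.

## The synthetic generator

`simulate_bundle()` generates every pipeline input with known ground
truth. Design choices, fixed once:

* **Scale.** 8 herbs × 20 compounds, a 300-node PPI, a 120-protein
  target pool. Large enough that medians and tails behave like real
  tables, small enough that the full test suite runs in seconds.
* **Compound panel.** OB ~ Uniform(0, 80) % and DL ~ Beta(2, 5) put
  roughly 40 % of compounds past the screen, mirroring the published
  keep-rates of OB/DL screens; 5 % of DL values are missing; 15 % of
  compounds map to no target. Each compound belongs to one primary
  herb and, with probability 0.15, to one-to-three others — herbs
  share constituents in real formulas.
* **Compound–target map.** Per-compound target counts are
  `1 + NegBin(size 1, mu 7)` and targets are drawn by linear
  preferential attachment, giving the heavy-tailed, hub-dominated
  bipartite degree distributions seen in real compound–target data.
* **PPI and planted module.** A Barabási–Albert graph (3 edges per
  node) carries a 15-node module wired pairwise at density 0.9. The
  module is sampled from the top of the degree ranking (twice the
  module size wide): disease-relevant proteins sit high in PPI degree
  distributions, and the filter this generator must exercise is
  hub-seeking by construction. Prototyping showed that a module
  planted on uniformly random nodes sits off the network's
  communication backbone and its interior systematically fails the
  betweenness median regardless of other settings — such a generator
  could not fulfil its purpose of providing a recoverable ground
  truth.
* **Disease lists and terms.** Five sources each include every module
  gene with probability 0.8 plus 10–50 background genes, emulating
  curated lists of very different sizes that overlap on the true
  disease core. Three planted terms of 10–12 module genes (plus 3
  background genes) sit among 30 random background terms of 10–40
  genes.

Recovery of the planted module is asserted as Jaccard similarity
(≥ 0.6 on the default seed-42 bundle), not exact equality: median
thresholds interact with background hubs, so a handful of extra or
missing nodes is expected behaviour, not failure. What passing this
shows about real data is limited in the usual ways: real PPI snapshots
have database-specific biases, real OB/DL distributions are not
uniform/Beta, and real disease lists are not conditionally independent
samples; the generator validates the machinery, not the biology.

All sampling flows from a single integer seed through R's RNG, so a
fixed configuration reproduces the bundle byte for byte; an
independent `recount_oracle()` recomputes every headline count by
naive enumeration for use as a test oracle.

## Degenerate inputs and numerical notes

Empty graphs error explicitly (`"no nodes"`); a stage-1 filter that
keeps nothing warns and returns an empty network, and downstream
stages refuse empty input. Self-loops are dropped on read (the
centrality definitions assume simple graphs); duplicate edges
collapse. Closeness and EC are per-component by construction, so
disconnected inputs need no special-casing, and single-vertex
components get EC 1 (their own unit vector). All thresholds appear in
`explain_thresholds()` with provenance (`config` vs `computed`).

## Known limitations

* Symbol-level identity is assumed throughout; protein isoforms or
  cross-identifier aliases are not reconciled.
* One-hop expansion is the only implemented neighborhood (besides
  none); deeper expansions would need explicit depth control.
* Betweenness on very large intersections is the slowest step; the
  package targets desk-scale networks (thousands of nodes).
* The enrichment universe choice dominates p-values; comparisons
  across runs are only meaningful under the same universe policy.
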