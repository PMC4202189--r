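---
title: "Shared pathway components via the bipartite edge-pathway model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared pathway components via the bipartite edge-pathway model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathbic)
```

## The model

`pathbic` compares a collection of biological pathway networks by what they
share at the level of interactions rather than gene membership. Each
pathway is reduced to a set of discrete gene–gene edges; each distinct
canonical edge receives one integer id; and the collection becomes a
bipartite graph linking edge ids to the pathways containing them. Two
pieces of structure are then extracted:

* **Maximal bicliques** (E, P): every edge of E lies in every pathway of P,
  and neither side can be extended. These are exactly the subgraphs shared
  by exactly a group of pathways. Because bicliques are closed, for any two
  of them P-containment runs opposite to E-containment, so the set of
  bicliques carries a natural partial order.
* **The hierarchical similarity graph**: the Hasse diagram (transitive
  reduction) of strict pathway-set containment over the bicliques. Its
  roots are the subgraphs shared by the most pathways; each step down
  narrows the sharing group and grows the shared subgraph.

The assumptions are deliberately spartan. Edges are undirected and
untyped: interaction semantics in the input are discarded, because nothing
downstream consumes them and keeping them would split edges that are
biologically the same association. Self-loops are dropped (with a count):
the bipartite model has no use for them. Edge weights, stoichiometry and
direction are out of scope.

## Decomposition of mixed graphs

Pathway files usually mix genes with non-gene entities — complexes,
small molecules, reaction nodes. A gene pair becomes an edge when the
genes are (a) directly adjacent, or (b) joined by a contiguous
uninterrupted path whose internal nodes are *all* non-gene. "Uninterrupted"
is formalized as: an intermediate gene breaks the path, so no edge is
drawn across it — the information that two genes talk *through a third
gene* is already carried by the two shorter edges.

Implementation is a breadth-first search from each gene that expands only
through admissible non-gene nodes; since a shortest all-non-gene path
exists whenever any does, BFS reach within the bound is equivalent to the
all-simple-paths definition (the test suite checks this equivalence
against a literal simple-path enumerator on random mixed graphs).

Tunable parameters:

| parameter | default | meaning |
|---|---|---|
| `max_internal_path` | 3 nodes | longest run of internal non-gene nodes that may be contracted; 0 keeps direct edges only. A small default keeps contraction local: long runs through shared molecular machinery connect genes that have no specific relationship. |
| `blacklist` | empty | non-gene nodes never traversed. Intended for currency metabolites (ATP, water, NAD+), whose hub degree would otherwise contract most of a metabolic map into a clique. |
| `unmapped_policy` | `keep-as-gene` | nodes absent from the identifier mapping: `drop`, `keep-as-nongene`, or keep under the original id as a gene. The permissive default loses nothing when no mapping is supplied; `drop` is the right choice for strict cross-species harmonization. |

Identifier comparison is case-sensitive and whitespace-trimmed, and all
ordering in the package (canonical pair orientation, edge-id assignment,
every exported file) uses byte order, never locale collation —
determinism over convenience.

## Biclique enumeration

The enumerator is closure-based, in the style of formal concept analysis:
the family of pathway sets obtained by intersecting the per-edge pathway
memberships is exactly the family of closed pathway sets, and each closed
set P pairs with the set of all edges contained in every member of P. This
was chosen because the pathway side of the incidence is small compared
with the edge side, making intersections over pathway sets cheap; the
number of closed sets, not the edge count, drives the cost. Correctness is
defined by an independent brute-force oracle (`oracle_enumerate_bicliques`)
that enumerates all pathway subsets, closes and deduplicates — refusing
more than 15 pathways — and the suite requires set equality between the
two routes on hundreds of random incidences.

Thresholds default to `min_pathways = 2`, `min_edges = 1`: a component
shared by a single pathway is not "shared", and below two pathways every
pathway's whole edge set would enter as noise. Output is sorted by
(pathway count desc, edge count desc, pathway ids) and numbered, so equal
inputs give byte-identical outputs.

## The hierarchy and its reading

The ordering of bicliques is not defined by any single figure convention;
containment of pathway sets is the only order consistent with both the
shared-subgraph view and the pathway-group view, so the package uses its
Hasse diagram, computed by an O(n³) reduction over the containment
relation (biclique counts are small: one per closed pathway set above
threshold). Levels are longest-path depths from the roots, so a node is
never drawn on the same rank as an ancestor. Multiple roots are permitted
— incomparable sharing groups simply form a forest with cross-links — and
nodes are restricted to maximal bicliques; no intermediate non-maximal
intersection nodes are synthesized.

`subhierarchy()` reroots on any node and recomputes levels;
`pathway_view()` relabels nodes by their pathway groups, giving the nested
organization of the original pathways that emerges from their shared
edges.

## Components, augmentation, coloring

Each biclique's edge set spans a gene graph that is usually disconnected,
so connected components are computed by repeated breadth-first search
over an adjacency list (linear in nodes plus edges; validated against a
union-find oracle) and the largest component is selected, ties broken by
the lexicographically smallest member so selection is deterministic — the
underlying choice is arbitrary and any fixed rule would do.

Root graphs are augmented before their largest component is computed: the
edges of every hierarchy node within two levels below the root are added.
"Two levels" is measured on the hierarchy's own depth assignment
(descendants at relative depth 1 and 2), not on distance in the gene
graphs — the augmentation exists to give the root's display the
interpolated context of its immediate refinements, which is a property of
the hierarchy. Note this use of "interpolated" is display-time edge union,
distinct from ingest-time path contraction, though both fill in context
around a sparse core.

Genes in at least one largest component are colored by the minimum-level
node whose largest component contains them, level ties broken by smallest
biclique id; the color index cycles a fixed 12-color palette by biclique
id. Genes outside every largest component stay uncolored (exported with a
null color) rather than inheriting a parent's color — coloring is a claim
of membership, and inheriting would forge one.

## The synthetic generator

`generate_collection()` plants "kernels": blocks of edges assigned to
prescribed pathway groups, plus pathway-private noise edges, with every
edge drawn distinct. When the kernel groups form a laminar family (any two
disjoint or nested), the expected biclique set has a closed form — one
biclique per distinct kernel group S, carrying the edges of every kernel
planted on a superset of S — so recovery can be scored without trusting
any enumerator. Non-laminar plans are allowed; their ground truth is then
produced by the brute-force oracle instead. Gene labels are zero-padded
(`g0001`, ...) so byte and numeric order agree.

The default conditions (`default_synth_spec()`): 8 pathways over 60 genes,
kernels of 1 edge on all 8 pathways, 3 edges on pathways 1–4 and 4 edges
on pathways 1–2, plus 5 private noise edges per pathway. This emulates the
situation the method is built for — a small core interaction shared
broadly, refined by progressively narrower shared subgraphs — at a scale
where every stage is inspectable by hand. What the generator does *not*
emulate: realistic pathway topology (hubs, scale-free degree
distributions, currency metabolites), partially-overlapping rather than
nested sharing in the default plan, incomplete identifier mappings, or
missing nodes/edges between redundant pathway curations. Passing tests
therefore demonstrate algorithmic correctness of decomposition,
enumeration, ordering and component analysis — not robustness of
biological conclusions to curation noise, which on real data will
fragment shared subgraphs into smaller bicliques than an ideal curation
would give.

## Numerical and degenerate-input choices

There is no floating-point tolerance anywhere: the pipeline is exact
integer/set computation. The degenerate cases are handled as: empty SIF
stream → empty graph, not an error; pathway with zero gene edges →
excluded with a warning; empty biclique set → empty hierarchy and empty
exports with exit code 0; duplicate pathway ids, malformed SIF lines and
non-functional mappings → input errors; a catalog whose ids are not a
canonical consecutive bijection → integrity error. The staged CLI maps
these classes to exit codes 2 and 3.

Test problem sizes — random incidences up to 10 pathways × 30 edges,
mixed graphs up to 12 nodes, component graphs up to 15 nodes, 50 generator
seeds, 200 repetitions per property — were chosen so the brute-force
oracles (2^p subset enumeration, all-simple-paths search) stay exact and
the whole suite runs in about a minute; the properties they check are
size-independent.

## Known limitations

* Biclique counts are exponential in adversarial incidences; the
  closure-based enumerator is meant for pathway-scale collections
  (hundreds of pathways), not arbitrary dense bipartite graphs.
* Interaction direction and type are discarded by design; analyses that
  need them (signed signaling logic) need a different edge model.
* Identifier harmonization is consumed as a given mapping table; the
  package does not infer homology or cross-reference clusters.
* The hierarchy orders bicliques only; it does not align pathway *names*
  or ontology terms — any emergent ontology is an output to inspect, not
  a computed alignment.

## A complete run

```{r example}
col <- generate_collection(default_synth_spec(seed = 1))
fit <- pathbic(col$edge_lists)
summary(fit)
score_recovery(fit$bicliques, col$truth, fit$catalog)
plot(fit)
```
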