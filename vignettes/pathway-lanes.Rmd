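---
title: "Merged pathway graphs with membership lanes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merged pathway graphs with membership lanes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathlanes)
```

This vignette documents the models, algorithms and design choices behind
`pathlanes`. The package turns multi-pathway biological data into a
single node-deduplicated directed graph, computes a layered layout with
per-pathway edge lanes, answers the standard interactive-exploration
queries as pure functions, and renders any view state to SVG.

## From reactions to relationship edges

A biochemical reaction is a hyperedge with input and output participant
sets. We reduce it to binary *reaction relationships*: A → B exists in
pathway P iff P owns at least one reaction with A among its inputs and B
among its outputs. `build_relationships()` expands a reaction to the
full input × output Cartesian product:

```{r}
build_relationships(reaction("rx", c("A", "B"), c("C", "D"), "P"), "P")
```

Two choices here were genuinely open:

* **Self pairs.** An entity appearing on both sides of a reaction would
  produce an A → A edge, which has no meaningful lane or tip geometry in
  this visual encoding; we drop it.
* **Within-pathway deduplication.** The relationship is defined by "at
  least one reaction", so several reactions yielding the same
  (source, target, pathway) triple collapse to one edge. Because a
  biologist may still want to know *which* reactions an edge summarizes,
  the originating reaction ids are retained in the edge table's
  `reactions` column.

`build_graph()` merges all pathways without duplicating nodes: entities
are keyed by exact id string equality (merging by name across databases
is out of scope), so an entity present in k pathways is one node with k
memberships.

### Sub-pathway aggregation

Pathways may nest. We treat membership in a sub-pathway as implying
membership in every ancestor: `memberships()` returns the transitive
closure upward, and a drawn element takes the color of its own pathway
when that pathway is visible, otherwise of its nearest visible ancestor.
This matches the behaviour of an expandable pathway list in which
collapsing a sub-pathway reassigns its elements to the parent's color.
Whether a sub-pathway's edges should *also* be drawn in the parent's
color when both are visible simultaneously is not forced by anything in
the data model; we chose the closure rule above, which keeps "hide the
child, keep the parent" monotone and needs no special cases.

## Layered layout

The drawing should flow from top to bottom, matching edge direction
wherever the graph allows it. A force-directed layout alone cannot
guarantee that, so we use a layered (Sugiyama-style) skeleton and apply
force relaxation only *within* layers:

1. **Feedback arcs.** Real pathways contain cycles, so some edges must
   point upward. We compute a linear arrangement with the greedy
   Eades–Lin–Smyth heuristic (repeatedly peel sinks to the back and
   sources to the front, otherwise take the vertex maximizing
   out-degree minus in-degree; ties broken by ascending id). Edges
   pointing backward in the arrangement form the feedback set — at most
   half the edges, usually far fewer; a 3-cycle loses exactly one edge,
   which is optimal.
2. **Layering.** Feedback edges are reversed and longest-path layering
   assigns each node the length of its longest incoming chain, putting
   sources in layer 0.
3. **Horizontal order.** Barycenter sweeps (default 4, alternating
   downward and upward) reorder each layer by the mean position of its
   neighbours. The sweep result is kept only if it does not increase the
   measured straight-line crossing count, so refinement can never make
   the initial ordering worse.
4. **Force relaxation.** Each node's x coordinate moves toward the mean
   of its neighbours (step 0.3, 30 iterations) with a small seeded
   jitter (±0.01 units) to break symmetric ties reproducibly. A final
   overlap-removal pass restores the minimum separation (default 40
   units) within each layer, preserving order.

All coordinates are abstract units with y growing downward (the SVG
convention); the layer gap defaults to 80 units. Every tie-break in the
pipeline is by ascending node id and the only randomness is the seeded
jitter, so a (graph, params, seed) triple yields byte-identical output —
a property the test suite asserts on serialized layouts and SVG.

`crossing_count()` counts properly intersecting centerline pairs
excluding pairs that share an endpoint; it is the objective used to
accept or reject the barycenter phase and is validated against an
independent brute-force segment-intersection oracle in the tests.

### Edge lanes

Parallel edges between a node pair are grouped by unordered pair
(`edge_groups()`); each pathway contributes one lane, ordered by the
pathway's color index then id so renders are stable. A pathway with
edges in both directions collapses to a single lane drawn with a sharp
tip at both extremities. Lane polylines are offset symmetrically about
the centerline at the configured spacing (default 6 units), so k lanes
occupy offsets (i − (k+1)/2)·s.

## Hierarchy inspection

Protein complexes are nested containment trees (proteins are leaves).
Two coordinated views support their inspection:

* `pack_overview()` — the unlabeled symbolic overview: complexes as
  rectangles, proteins as dots, children strictly inside their parent.
  Nothing in the visual design dictates a specific packing, so we use a
  deterministic shelf grid per nesting level (children in model order,
  rows of ⌈√n⌉ cells, fixed padding 0.25 units): byte-stable output was
  preferred over aesthetic area optimization. Labels are deliberately
  absent here — they live in the pruned tree.
* `prune_tree()` — the labelled detail view: the chain from the root
  down to the selected element's parent, plus all of that parent's
  components. Children are reported in model (component list) order; the
  data gives no principled ordering by size or name, and model order
  preserves whatever the source database considered canonical.
  Selecting the root itself is a degenerate case we define (empty chain,
  root as sole child) rather than an error, so hover sweeps are total.
* When an element sits under several sub-complexes of one root, every
  geometric instance can be highlighted in the overview, but the pruned
  tree reports one canonical witness path: the lexicographically first
  id sequence (`occurrences()` uses the same rule).

Styling follows the two-intensity convention: nested complexes alternate
two intensities of a single hue, and the selected element turns gray —
one hue keeps the hierarchy view from fighting the pathway palette.

## Interaction queries

All queries are pure functions of `(graph, view_state)`; expansion
operations return explicit deltas applied with `apply_delta()`, which
both makes CLI sessions replayable and leaves room for an undo stack
later without redesign.

* **Keyword filtering** is case-insensitive substring matching — the
  loose queries biologists actually type ("ORC1-6", "Ubiquitin") are
  substrings, not regular expressions or exact tokens. A complex matches
  through its own name or any transitively contained protein's name
  (nested sub-complex names alone do not match; only protein names
  propagate). An empty keyword list disables the filter instead of
  hiding everything.
* **Visibility**: a node is drawn iff it is revealed, belongs to at
  least one visible pathway (under the aggregation closure), and passes
  the keyword filter; edges additionally need both endpoints visible.
  Hiding pathways is monotone: the visible set can only shrink.
* **Upstream/downstream steps** return the unrevealed visible-pathway
  adjacency of a node; `hidden_step_markers()` reports, per node,
  whether unrevealed in- or out-edges remain (the up/down triangles).
* **Intermediate steps** between s and t: we return the nodes reachable
  from s from which t is still reachable, plus all visible edges among
  them. On acyclic graphs this equals the union of all simple s→t paths
  (asserted against exhaustive path enumeration in the tests). On cyclic
  graphs the reachability-intersection definition additionally includes
  cycle nodes sitting between the endpoints even when every walk through
  them repeats a node; we chose it because the semantics of "all of the
  relationships between the two" favours inclusiveness and it runs in
  linear time, whereas simple-path enumeration is exponential.

## Rendering

`render_svg()` draws circles for proteins, squares for complexes, and
one concentric border ring per visible pathway membership. Concentric
rings (innermost = lowest color index) were chosen over side-by-side
arcs because the encoding is unambiguous at any ring count and the order
is stable. Hovering desaturates every element not sharing a pathway with
the target to a fixed light gray — a constant, rather than per-color HSL
manipulation, keeps output deterministic — and labels are emitted only
for the hover context (or everywhere with `always_label`, an explicitly
requested option). Labels are placed right of their node with no
collision resolution; proper label layout is future work. Enlarged
complexes are drawn as their packed overview scaled into the diagram,
with neighbours pushed radially until the minimum separation holds.
The default palette holds 8 qualitative colors; with more
simultaneously visible top-level pathways, colors recycle with a
warning.

## The synthetic generator

`generate_fixture()` emulates a multi-pathway analysis session — several
pathways with controllable entity overlap, a complex fraction with
bounded nesting depth, and reactions following an acyclic rank skeleton
with a controllable probability of back-edges that create feedback
cycles. Defaults (6 pathways, 60 entities, 20% overlap, 30% complexes,
depth ≤ 3, 40 reactions, 10% cycle edges) were chosen as a desk-scale
version of a realistic cell-cycle session: enough overlap that shared
nodes matter, enough cycles that feedback handling is exercised.
Generation is a pure function of the seed (the caller's RNG state is
untouched), and entity names draw on a fixed vocabulary of
DNA-replication actors (ORC1–6, CDC6, MCM2–7, …) so keyword examples
read naturally.

What the generator does **not** emulate: realistic degree distributions,
reaction stoichiometry, cellular compartments, or curated database
content. Passing tests on these fixtures therefore demonstrate the
engine's structural guarantees (deduplication, layering, query
semantics, serialization identity), not biological fidelity of any
specific pathway.

BioPAX note: the Level-3 reader covers Pathway, BiochemicalReaction
(left → inputs, right → outputs; reversibility semantics beyond the
both-direction lane collapse are out of scope), Protein and Complex;
other physical entities import as protein-kind nodes tagged with their
class, and unknown classes are skipped and reported, never fatal.
BioPAX has no construct for a pathway's entity membership independent of
reactions, so the write/read identity holds on the model restricted to
reaction-witnessed membership (`biopax_subset()`); the JSON dialect is
the lossless source of truth.

## Problem sizes and limitations

The test suite runs at desk scale: fixtures up to 10 pathways × 200
entities for deduplication properties, 100 random DAGs of ≤ 12 nodes for
the exhaustive path-enumeration oracle, and graphs of ≤ 50 edges for the
brute-force crossing oracle — sizes where the independent oracles are
exact and fast. Known limitations: crossing minimization is heuristic
(the underlying problem is NP-hard); simple-path equivalence of the
intermediate-step query is only guaranteed on acyclic inputs; label
placement does not avoid collisions; and the BioPAX subset ignores
Catalysis/Control semantics, stoichiometry and cellular locations.
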