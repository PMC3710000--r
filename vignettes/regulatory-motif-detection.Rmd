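---
title: "Detecting regulatory motifs in signed signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting regulatory motifs in signed signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmotif)
```

## The problem

A signaling network is a signed directed graph: nodes are molecules
(mostly proteins), and an edge `A → B` with sign +1 means A converts B to
its active form, sign −1 that A inactivates B. Dynamic regulatory
properties — oscillation, adaptation, bistability — are generated by small
circuit topologies of such signed edges, established by mathematical
modeling studies as 2–3-node *regulatory motifs*. In curated networks the
same circuits appear stretched over cascades: a negative feedback loop of
three, five or eight molecules is dynamically the one motif, because a
cascade's net regulatory effect is the product of its edge signs. Direct
induced-subgraph matching of the minimal topologies therefore misses most
realized motifs. `regmotif` closes that gap by compressing the network
before matching and expanding matches afterwards.

## Network model and input format

`read_network()` parses the 3-column exchange format (regulator, relation
∈ {`+`, `-`}, target; whitespace separated, `#` comments). Validation
leaves at most one signed edge per ordered node pair. Interactions
reported with *both* signs are biologically inconsistent (typically
database-integration artifacts); the default policy removes every edge of
such a pair, a `"reject"`-style policy (`on_conflict = "error"`) is
available for strict pipelines. Self-loops are legal and carry signs.
Node identifiers are arbitrary non-whitespace strings compared exactly.
Isolated nodes are representable in memory but not in the 3-column format,
so `write_network()` warns and omits them. `degree_profile()` labels
boundary nodes with the neutral terms *source* (only outgoing edges) and
*sink* (only incoming); note that some network viewers call sink nodes
"input nodes" and source nodes "output nodes", so the package avoids the
input/output vocabulary altogether rather than silently picking one
convention.

## Step 1 — compression by node-based reduction

`compress_network()` eliminates a node `v` and reconnects each
predecessor–successor pair `(p, s)` with a bypass edge of sign
`σ(p,v)·σ(v,s)`. Eligibility is deliberately conservative:

* `v` is not protected and has no self-loop (a self-loop is itself a
  regulatory circuit; removing the node would destroy it);
* `v` has at least one predecessor and one successor (boundary nodes are
  the network's inputs/outputs and must survive);
* `v` lies on a linear segment: `in_degree == 1` or `out_degree == 1`.
  This *unit-degree gate* is exactly linear-cascade reduction — the
  motivation for compressing at all — and bounds bypass growth to
  `max(|P|, |S|)` new edges. Disable with `unit_degree_gate = FALSE` to
  allow full `|P|·|S|` clique bypasses;
* no bypass edge conflicts in sign with an existing or co-created edge on
  the same ordered pair. A conflict aborts the *whole* elimination of
  `v` — dropping one of the edges instead would silently change the
  network's dynamics.

Nodes are scanned in sorted-id order repeatedly until a pass eliminates
nothing, so the output is a deterministic fixpoint (idempotence is
tested). Collapsing a 2-cycle creates a self-loop on the survivor; this is
allowed by default (`allow_new_self_loops`) because compressed motif forms
include self-regulation, and expansion later restores true loop lengths.
Elimination order can in principle select among equivalent reductions;
correctness is therefore stated (and tested) as a soundness invariant —
every reduced edge is realized by at least one original path of matching
sign through eliminated nodes — rather than as equality of a particular
reduced graph.

For whole-network analysis nothing needs protection (matches are expanded
afterwards); path-constrained analysis protects the source and target.

## The motif library

`builtin_motifs()` ships compressed, pairwise non-isomorphic topologies in
three classes, stored as plain edge-list files under
`inst/extdata/motifs/` with a manifest, so the set can be curated without
code changes. The members follow the modeling literature on each class:
for oscillation, negative feedback loops at the compressed sizes the
reduction can produce (1-node negative self-loop, 2-node
activator–inhibitor loop) and their self-regulated variants (relaxation
oscillator cores); for adaptation, the negative-feedback-loop-with-buffer
and incoherent-feedforward-with-proportioner 3-node topologies; for
bistability, positive feedback in its compressed forms (autocatalytic
self-loop, mutual activation, double-negative mutual inhibition) singly
and coupled. The precise published figure sets for the three classes are
not fully reproducible from text sources, which is exactly why the
library is data, not code; the loader enforces the non-isomorphism
invariant on whatever the files contain.

The `min_size` annotation (shipped as the manifest's `min_size` column)
marks motifs whose dynamics require a minimum realized circuit size. A
pure negative feedback loop needs the delay of at least three components
to oscillate, so the 1- and 2-node negative-feedback forms carry
`min_size = 3`; forms with explicit positive self-regulation (relaxation
oscillators) and the bistable forms do not, since autocatalytic
bistability and 2-component relaxation oscillation are established at
small sizes. The flag is enforced at instantiation (an instance spanning
fewer distinct molecules is dropped), never during search — a deliberate
choice, since one compressed match can expand to instances of several
sizes.

`add_motif()` registers user motifs and rejects isomorphic duplicates,
reporting the clashing id.

## Canonical labels, isomorphs, and the path-tree

Signed isomorphism requires a node bijection preserving edge direction
*and* sign. For motif-sized graphs (≤ 6 nodes) the package enumerates all
`k!` node orderings outright — exact, dependency-free, and cheap at these
sizes; the limit exists because isomorph generation is factorial. The
canonical label reads the adjacency matrix in the node-incremental order
(for node *i*: `(i,i)`, then `(i,1..i-1)`, then `(1..i-1,i)`), giving the
entry sequence `(1,1),(2,2),(2,1),(1,2),(3,3),(3,1),(3,2),(1,3),(2,3)` at
`k = 3`; node *i* contributes `2i−1` entries. The canonical *form* is the
lexicographically smallest label under the entry order `0 < +1 < −1`
(sparse graphs sort early — any fixed total order would do). The sign
alphabet {0, +1, −1} matches the network's σ convention, with 0 meaning
"no edge", so induced matching compares absences too.

`build_path_tree()` inserts every isomorph label of every same-size query
motif into a trie whose level-*i* keys are the `2i−1` entries contributed
by node *i*; leaves carry motif ids. One tree is built per motif size and
the search runs once per size — consistent with the `k²`-length label
scheme, and it keeps `path_tree_step()` a single hash lookup.
Reconstruction of the label set from the leaves is a tested invariant.
Trees are rebuilt on demand; at `k ≤ 6` construction costs `k!` label
generations per motif and persistence would buy nothing.

## Step 2 — ESU search with trie pruning

`enumerate_connected_subgraphs()` implements ESU: nodes get integer
enumeration labels in sorted-id order; a subgraph grows from its root only
through exclusive neighbours with labels above the root's, which yields
every weakly connected *k*-set exactly once, from a single discovery
order. Connectivity is over the underlying undirected graph: signed
motifs are weakly connected, and enumeration tools for directed motif
search do the same. Self-loops never extend a subgraph but do appear on
induced diagonals.

`find_matches()` interleaves the trie: adding node *i* reveals exactly the
`2i−1` induced-adjacency entries the label scheme assigns to it, which are
fed to `path_tree_step()`; a dead end prunes the branch, a leaf at depth
*k* emits one match per motif id there. Because every isomorph of every
query is in the tree, the single ESU discovery order of a matching set
always reaches a leaf — pruning removes only non-matches (tested against
`prune = FALSE` runs, along with monotonicity of visited partials).
Matching is induced (exact-zero) semantics throughout, the semantics under
which a library of pairwise non-isomorphic same-size motifs partitions
matches (a node set matches at most one motif — asserted in tests, not
assumed).

## Steps 3–4 — expansion and instantiation

`expand_edge()` enumerates all simple original-network paths realizing a
compressed edge: internal nodes must be eliminated nodes and the sign
product must equal the edge sign. A direct original edge qualifies as the
length-1 path; expanding a self-loop permits start == end, recovering
collapsed feedback loops. The DFS is capped at `max_len = 8` edges per
path by default — unbounded expansion over a large eliminated set can grow
combinatorially, and eight edges per compressed edge is beyond any
realized cascade length we consider biologically interpretable;
configurable.

`instantiate_matches()` takes the Cartesian product of per-edge path
choices and keeps selections whose internal nodes are pairwise disjoint
and disjoint from the match nodes: overlapping paths would not realize
the motif's circuit topology as separate regulatory arms. A switch
(`allow_shared_internals`) relaxes this for exploratory use. Instances
are deduplicated by full edge multiset across matches, and all path
combinations are reported (instance-level counting), not one
representative per match. The `min_size` filter applies here.

## Pipeline, path-constrained analysis, and reporting

`analyze_network()` chains the four steps and returns a tidy report:
`tidy()` gives the per-edge instance table (path string `A>B>C`, sign,
length, size), `glance()` a one-row summary, `autoplot()` a per-motif
count figure, `write_report()` the TSV/JSON artifacts. Determinism is a
tested invariant: fixed scan orders everywhere make identical inputs give
identical reports.

`analyze_path()` restricts results to motifs along the routes between a
source and a target: it computes *all* shortest directed paths
(`shortest_paths_between()`, delegated to igraph's all-shortest-paths
machinery; source == target gives the zero-length path by convention) and
keeps instances whose compressed-match nodes lie within the paths.
"Included in the path" is genuinely ambiguous — within the union of all
shortest paths, or within one path? Both are exposed
(`path_scope = "union"` default, `"single"` stricter); the default favors
the union because parallel shortest routes jointly form the regulatory
corridor between the endpoints.

## Synthetic data and the oracle

`random_network()` draws exactly `m` distinct ordered pairs uniformly (no
sign conflicts by construction) with each edge inhibitory at probability
`negative_fraction = 0.18`, the inhibitory share of large integrated human
signaling networks; pathway-scale fixtures in the tests use 68 nodes / 89
edges, the size of a single-pathway network, and the scaling study spans
100–800 nodes at 2.3 edges per node, matching the sparse density of
curated pathway collections. What the generator does *not* emulate:
scale-free degree structure, pathway modularity, and the enrichment of
feedback loops that real signaling networks show — so passing tests
demonstrate algorithmic correctness on the stated graph model, not
biological yield on real data.

`oracle_matches()` is the semantics made executable: enumerate all
`C(n,k)` node subsets, compare each induced signed adjacency against all
`k!` permutations of the query matrix, using plain row-major flattening.
It shares no code with the canonical-label, path-tree or search modules,
which is what makes the agreement tests meaningful; its cost guards it to
`n ≤ 40`, `k ≤ 5`. The acceptance suite checks exact agreement of
`find_matches()` with the oracle over 20 seeded random networks × 50
sampled queries of sizes 3–5 each, and sub-quadratic growth (log-log
slope < 2) of median search time over 100–800-node networks — an
assertion robust to machine constant factors, unlike absolute run-times.

## Numerical and degenerate-input choices

* Ties and orders: node scans, neighbour lists, emitted matches, expanded
  paths and report rows all follow sorted-id/lexicographic order; no
  result depends on hash iteration.
* Degenerate inputs: empty edge files are errors (an edge list with no
  edges is almost always a format mistake); empty match sets, empty
  expansion lists and unreachable path queries are ordinary empty results
  (exit code 0 in the CLI), with a notice for the unreachable case.
* `k = 1` subgraph enumeration returns singletons, letting self-loop
  motifs participate in the same machinery as larger ones.

## Known limitations

* Motif size is capped at 6 (factorial isomorph generation); realized
  instances are unbounded in size, only the compressed query is capped.
* The compression rule set is the conservative linear-cascade reduction
  described above; more aggressive kernel-style reductions (and the
  edge-based reduction family) are out of scope.
* No statistical significance testing against randomized networks, and no
  dynamical simulation of detected instances: classes are assigned by
  topology, and whether a particular instance actually oscillates or
  switches depends on kinetics the network does not encode.
* The brute-force oracle bounds exhaustive validation to ~40-node
  networks; beyond that, correctness rests on the tested invariants.
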