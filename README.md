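# regmotif

Regulatory motif detection in signed directed signaling networks.

Signaling networks describe activation (`+`) and inhibition (`-`) between
molecules. Their dynamic behaviours — sustained oscillation, adaptation
(return to baseline after a stimulus), and bistable switching — are produced
by small signed circuit topologies: negative feedback loops, incoherent
feedforward loops, coupled positive feedback loops. In real networks these
circuits rarely appear in minimal form; they are stretched over cascades of
intermediate molecules, which makes them invisible to plain subgraph
matching.

`regmotif` finds them anyway, in four steps:

1. **Compression.** Node-based reduction eliminates intermediate cascade
   nodes, replacing each with bypass edges whose sign is the product of the
   signs along the removed segment (`σ(p,s) = σ(p,v)·σ(v,s)`), so the
   reduced network preserves the sign dynamics of the original
   (`compress_network()`).
2. **Search.** All induced occurrences of compressed 2–3-node query motifs
   are enumerated with ESU — every weakly connected *k*-set is generated
   exactly once — pruned by a *path-tree*: a trie over canonical labels of
   all isomorphs of the query motifs. The canonical label linearizes a
   *k*×*k* signed adjacency matrix node-incrementally (for node *i*: entry
   (*i*,*i*), then row (*i*,1..*i*−1), then column (1..*i*−1,*i*); 2*i*−1
   entries per node), so each node added during the search is checked with
   a single trie lookup (`build_path_tree()`, `find_matches()`).
3. **Expansion.** Each matched compressed edge is expanded back into
   original-network paths by a depth-first search under two constraints:
   internal nodes must be eliminated nodes, and the path's sign product
   must equal the compressed edge's sign (`expand_edge()`).
4. **Instantiation.** Concrete motif instances are assembled by choosing
   one path per edge (internally disjoint), annotated with per-edge sign
   and length and total size (`instantiate_matches()`).

The package ships a compressed motif library for the three regulatory
classes (`builtin_motifs()`), a synthetic network generator, and a
brute-force matching oracle (`oracle_matches()`) that anchors the test
suite.

## Worked example

A two-protein negative feedback loop (`A ⇄ B`) padded with a cascade
`A → X → B`. Compression collapses the whole graph to a single node with a
negative self-loop; searching the compressed network and expanding the
match recovers the full three-molecule feedback circuit:

```r
library(regmotif)
net <- read_network(c("A + B", "B - A", "A + X", "X + B"))
rep <- analyze_network(net)
rep
#> <regmotif_report> 1 match(es), 1 instance(s) of 12 queries
#> <compressed_network> 3 -> 1 nodes, 4 -> 1 edges (2 eliminated)
#> # A tibble: 1 × 5
#>   motif_id    class        size n_matches n_instances
#>   <chr>       <chr>       <int>     <int>       <int>
#> 1 osc_selfinh oscillation     1         1           1

tidy(rep)
#> # A tibble: 1 × 8
#>   motif_id    instance from  to     sign length path     size
#>   <chr>          <int> <chr> <chr> <int>  <int> <chr>   <int>
#> 1 osc_selfinh        1 B     B        -1      3 B>A>X>B     3
```

The detected instance is the oscillation-class motif `osc_selfinh` (a fully
compressed negative feedback loop): realized as the circuit `B>A>X>B` with
net sign −1, path length 3 edges, spanning 3 molecules. The two-molecule
loop `B>A>B` is also present but suppressed: a pure negative feedback loop
needs at least three components to oscillate, which the motif's
minimum-size annotation enforces. The same analysis is available from the
shell via the thin CLI at `inst/cli/regmotif`
(`analyze`, `analyze-path`, `compress`, `motifs`, `gen`).

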