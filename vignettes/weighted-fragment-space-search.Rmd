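---
title: "Weighted similarity search in topological fragment spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted similarity search in topological fragment spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragsim)
```

## The problem

Make-on-demand compound collections encode billions of molecules as
*topological fragment spaces*: a set of topology graphs whose nodes hold
interchangeable building-block fragments and whose edges state how fragments
of adjacent nodes connect (via named linker placeholder atoms, with a defined
bond order). A product molecule is one fragment per node, wired along the
edges; the library size is the product of node sizes, so it is never
enumerated.

Similarity search in such a space asks for the N products most similar to a
query molecule under a fingerprint Tanimoto coefficient, computed without
enumeration by working on the building blocks. `fragsim` implements that
search and a *weighted* extension: the user marks query atoms (a SMARTS match
or an explicit atom list) and the search up-weights fingerprint features made
of marked atoms, enriching results that preserve the marked substructure
while allowing variation elsewhere.

## Fingerprints and similarity

Two sparse count descriptors are provided.

* `csfpA.B`: one feature per connected induced subgraph with A to B atoms.
  Feature identity is an exact canonical signature of the labelled subgraph
  (element, charge, aromaticity, bond orders), minimised over vertex
  permutations in compiled code — no lossy hashing, so identical subgraphs
  collide exactly and nothing else does. The default `csfp1.4` uses sizes
  1–4.
* `ecfpD`: circular environments for radii 0..D/2 with an exact recursive
  neighbourhood signature per layer (element, charge, aromaticity, heavy
  degree, H count at radius 0). Layers are not deduplicated; each records the
  atom set it covers, which marking needs.

Similarity is the count-vector Tanimoto (Ruzicka) coefficient
`sum_i min(x_i, y_i) / sum_i max(x_i, y_i)`, 0 for no common features and 1
for identity. Two empty fingerprints give 0 by convention, so empty fragments
never rank as perfect matches.

**Weighting.** Given a marked atom set, every fingerprint feature consisting
entirely of marked atoms forms the set M; the weight function assigns
`w(i) = k` for features in M and 1 otherwise, and the weighted coefficient is
`sum w(i) min / sum w(i) max`. For integer k this equals the plain
coefficient with marked counts replicated k-fold, which the test suite uses
as an independent oracle. Two refinements, both off by default:
`min_feature_size` exempts features below a size floor from up-weighting
(small one/two-atom features are unspecific and add noise), and
`weight_by_size` multiplies each marked feature's weight by its heavy atom
count (a size-4 feature at k = 5 weighs 20), favouring the larger, more
specific parts of a marked area.

Placeholder atoms — fragment linkers, ring-padding dummies and the wildcard
caps added to cut query substructures — enter fingerprints as a wildcard
element. A fragment's border feature (anchor atom + linker) therefore equals
the query class's border feature (atom + cap), which is what makes
fragment-versus-substructure comparison meaningful. Wildcard-containing
features are never members of M, and a feature's "size" for the two
refinements counts real atoms only.

## The search

1. **Partitioning.** Acyclic single bonds of the query are cut in all ways
   that produce as many connected partition classes as some topology graph
   has nodes, with class adjacency isomorphic to that graph (bond types
   included). Aromatic and ring bonds are never cut, and graphs containing
   ring-formation edges are skipped by the matcher (product assembly still
   supports them; their partitioning semantics would be ill-defined).
2. **Matching.** For each partition and graph, every class/node bijection is
   checked by exhaustive search (topology graphs are tiny): equal topology,
   equal per-class connectivity, and a size filter — a class must be within 5
   heavy atoms (`size_slack`) of at least one fragment of its node.
3. **Comparison.** Each node's fragments are ranked by the weighted Tanimoto
   between the fragment fingerprint and the wildcard-capped class
   fingerprint. M is computed *per class*, from features both fully marked
   and present in the class fingerprint. Marked features outside the class
   would otherwise inflate only the denominator and penalise fragments for
   not containing something the class does not contain either.
4. **Combination.** A combination picks one ranked fragment per node; its
   score is the share-weighted sum of partial scores, where a class's share
   is its (adjusted) atom count over the query's total. With weighting, each
   marked atom counts as `k / c` atoms (correction factor `c`, default 3), so
   a small class holding the marked area is not drowned out by large
   unmarked classes. The top-P combinations (P = `pool_multiplier` × N,
   default 10 × N) are enumerated lazily, best-first over the ranked lists:
   the pool provably equals the brute-force top-P, which the acceptance suite
   verifies by exhaustive enumeration.
5. **Global re-ranking.** Pool combinations are assembled into full products
   and re-scored by weighted Tanimoto against the whole query, with M now
   computed on the whole query. Marked features spanning several fragments
   appear here for the first time, rewarding products that reassemble the
   complete marked area rather than disconnected parts of it. The best N
   distinct fragment selections are returned.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `n_results` (N) | 10 | hits returned |
| `descriptor` | `csfp1.4` | fingerprint variant |
| `k` | 1 | weighting factor for marked features (1 = unweighted) |
| `correction` (c) | 3 | divisor of k in adjusted atom counts |
| `min_feature_size` | 1 | smallest feature size eligible for weighting |
| `weight_by_size` | FALSE | multiply weights by feature size |
| `size_slack` | 5 | heavy-atom slack of the matching size filter |
| `pool_multiplier` | 10 | candidate pool = multiplier × N |

The defaults reproduce the reference configuration; `c = 3` was chosen there
empirically as a balance between preserving marked features and overall
similarity, and k = 6 with c = 3 makes each marked atom count as 2 atoms.

### Numerical and design choices

* **Adjusted count floor.** A marked atom counts as `max(1, k / c)` atoms.
  The plain `k / c` would make marked atoms count *less* than unmarked ones
  for k < c and would violate the exact-reduction contract (k = 1 must equal
  the unweighted search in every intermediate quantity). The floor leaves
  every published value (k ≥ 3) unchanged.
* **Tie-breaking** is total and deterministic everywhere: fragments by
  (score desc, id), combinations by (score desc, graph id, fragment id
  tuple, matching index), hits additionally deduplicated by node→fragment
  selection. Identical inputs give byte-identical output files.
* **Aromaticity as written.** The SMILES layer does not perceive or
  kekulise aromaticity; molecules are compared under one consistent writing
  convention (all bundled data and all generated fragments use aromatic
  form). Canonical identity is an exact graph code computed by partition
  refinement with individualization backtracking.
* **Ring formation.** An aromatic ring split across two fragments is
  represented at full size in both (partner atoms as placeholders) and
  completed on assembly by a pair of ring-formation edges joining the two
  real anchor pairs; all placeholders then vanish. Only rings completed
  between exactly two fragments are supported.
* **Degenerate inputs.** Empty molecule → empty fingerprint; two empty
  fingerprints → similarity 0; a query with no compatible topology → empty
  result with a warning; a marking SMARTS with zero matches → an error
  (nothing to weight).

## The synthetic benchmark

Real vendor spaces are proprietary and billions strong; the bundled
generator emulates their structure at desk scale. Each of ~50 bundled
drug-like molecules (filtered to at most one violation of the computable
Lipinski criteria — MW, donors, acceptors; logP needs external tables and is
treated as satisfied) is cut at 1–2 random acyclic single bonds; the pieces,
capped with linkers, are pooled by chain position into the nodes of 2- and/or
3-node chain topology graphs. Two properties follow by construction: every
source molecule is a product of the space (ground truth for identity
recovery), and cross-combinations of pieces from different sources provide
the near-analogs a similarity search needs. With the full bundled set this
gives ~3×10^4 products from ~140 fragments.

What the generator does *not* emulate: reaction chemistry (cuts are
topological, not retrosynthetic), ring-forming connections, node pools with
thousands of fragments, and the extreme N-to-space-size ratio of real spaces.
A green benchmark therefore establishes that the weighting mechanism enriches
marked substructures under realistic drug-like chemistry, not that the
published billion-scale numbers are reproduced.

Benchmark cases are (query, SMARTS) pairs: queries are source molecules;
patterns are random connected substructures of 3–7 atoms, rings included
whole (whole ring *systems*, a stricter and simpler rule than per-ring
closure), at least one non-carbon atom, extracted as element +
ring-membership SMARTS with explicit bond orders. After searching, cases are
discarded when no search found any matching molecule (the space cannot serve
the case) or when the unweighted search already preserves the pattern in
100% of results (nothing to improve). The preservation score of a search is
the fraction of its hits matching the pattern. On the default configuration
the mean preservation score rises monotonically in k; the acceptance suite
requires a strict improvement from k = 1 to k = 10 and non-decreasing means
across k ∈ {1, 5, 10, 20} within a sampling tolerance of 0.02 (absorbs
per-case granularity of 1/N at N = 10 over ≥ 50 kept cases). On the suite's
configuration (140 sampled cases, 57 kept) the computed means are 0.55, 0.77,
0.84 and 0.91 for k = 1, 5, 10, 20, declining with pattern size within each
k, and the weighted-minus-unweighted gap is present at every pattern size.

## A worked example

```{r example}
space <- generate_space(synthetic_space_spec(bundled_molecules()[1:10],
                                             seed = 7))
space_size(space)
query <- attr(space, "sources")$smiles[5]   # nicotine
query
unweighted <- search_space(space, query, config = search_config(n_results = 5))
unweighted$hits[, c("rank", "smiles", "score")]
weighted <- search_space(space, query, smarts = "[n;R]",
                         config = search_config(n_results = 5, k = 10))
weighted$hits[, c("rank", "smiles", "score")]
```

The identity product returns at rank 1 with similarity 1 in both runs;
weighting the pyridine nitrogen shifts the remaining ranks toward products
that keep the pyridine ring.

## Known limitations

* SMARTS support is a documented subset (single predicates combined with
  AND/NOT; `R<n>` via a ring-bond-degree heuristic rather than SSSR);
  unsupported constructs raise errors instead of silently mismatching.
* No stereochemistry, isotopes, or tautomer handling; aromaticity is taken
  as written.
* Implicit hydrogen counts follow the standard valence tables; exotic
  valences fall back to zero implicit hydrogens.
* Per-node ranked lists are kept in full before combination (the reference
  implementation may truncate; the depth is not published). The candidate
  pool size of the global re-ranking step is likewise unpublished; it is the
  `pool_multiplier` knob here.
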