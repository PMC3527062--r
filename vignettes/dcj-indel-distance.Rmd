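---
title: "Computing DCJ-indel edit distances for genomes with duplicate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing DCJ-indel edit distances for genomes with duplicate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjindel)
```

## The model

`dcjindel` measures the separation of two gene orders under three unit-cost
operations:

- **DCJ** (double-cut-and-join): cut the genome at two points and rejoin the
  four ends — this one primitive subsumes inversions, translocations,
  fusions, fissions, circularizations and linearizations;
- **insertion** of a single gene (one new head-tail extremity pair,
  duplications included, since the inserted gene may belong to an existing
  family);
- **deletion** of a single gene.

A genome is reduced to its *adjacency set*: the multiset of adjacencies
(unordered pairs of extremities of consecutive genes) and telomeres (single
extremities at linear chromosome ends). The distance is defined **at the
adjacency-set level**. This matters for duplicated content: two genomes with
different chromosome structures can share one adjacency set, so the value
computed here is a lower bound on any structure-level distance; resolving
the structural ambiguity is outside the model.

Orientation convention: a gene written `+g` exposes its tail on the left and
its head on the right; `-g` the reverse. One convention had to be fixed for
parsing and realization; this is the one used throughout.

### From content differences to ghosts and caps

Let E₁, E₂ be the extremity multisets of the two adjacency sets S₁, S₂. The
surplus extremities E₁∖E₂ are paired **head-with-tail within each gene
family** into ghost adjacencies T₁ (genes that must be deleted from genome
1); T₂ symmetrically holds the pending insertions. Pairing within the family
is the only usable choice because a unit deletion removes exactly the
head-tail pair of one gene copy; cross-family ghosts could never be resolved
by a single operation. When a family has surplus greater than one, all
head/tail pairings within the family are interchangeable; a deterministic
one is used.

Telomeres are removed before optimization: every telomere `x` becomes an
adjacency `x·τ` with a null extremity τ, and `|k₂ − k₁|` null adjacencies
`ττ` pad whichever side has fewer telomeres (capping is symmetric even
though only one direction strictly needs the padding). Capping leaves the
distance unchanged and makes every decomposition of the adjacency graph a
set of cycles, which is what the 4-cycle packing step needs.

### The adjacency graph and the distance formula

The adjacency graph is bipartite: left vertices S₁′ ∪ T₂, right vertices
S₂′ ∪ T₁, with one edge per shared extremity occurrence (two edges when two
elements share both extremities). The package never materializes edges: a
*decomposition* is stored as a label-preserving bijection between left and
right extremity occurrences ("slots"), which automatically induces the
vertex-disjoint alternating cycles and paths that cover the graph.

A cycle of length ℓ is **helpful** when at most ℓ/2 − 1 of its vertices are
ghosts; with exactly ℓ/2 ghosts (necessarily all on one side, since T₁ and
T₂ never share extremities) it is unhelpful and saves nothing. The edit
distance equals

d(S₁, S₂) = n − max over decompositions of (c + o/2),

with *n* half the extremity count per side, *c* the number of helpful
cycles, *o* the number of odd paths. Maximizing the decomposition is
NP-hard, hence the two solvers below.

## The two solvers

### Brute-force oracle

`edit_distance(a, b, method = "exact")` enumerates decompositions by
branch-and-bound: components are built one at a time (always anchored at the
lowest free slot, so each matching is enumerated once), candidate partners
are deduplicated over interchangeable identical elements, and a bound
(remaining non-ghost elements per side, plus remaining telomere pairs for
paths) prunes hopeless branches. Two implementation choices matter:

- the oracle runs on the **uncapped** graph, enumerating paths directly.
  Capping would multiply the search space by the permutations of the
  interchangeable null extremities while leaving the optimum unchanged;
  that invariance is itself verified in the test suite by running both
  variants on over a hundred small telomere-bearing instances.
- the graph is first split into its connected parts (elements linked by
  shared labels), which are solved independently and stitched back.

The oracle refuses instances above `max_side` elements per side (default 12;
the acceptance suites raise it to 40, which stays comfortable because of
the component splitting).

### Approximation algorithm

`edit_distance(a, b)` (default) follows four steps on the capped graph:

1. build ghosts, cap telomeres, build the graph;
2. enumerate all **helpful 4-cycles** (two left and two right elements with
   at most one ghost among them, deduplicated by element set) and select an
   element-disjoint subset — 4-set packing. Packing is exact
   (branch-and-bound) up to `auto_limit = 24` candidates, otherwise greedy
   with Hurkens–Schrijver-style `(r, r+1)` swaps up to `swap_radius`
   (default 2). The classical polynomial (2+ε) packing algorithm is treated
   as a black box by the theory; substituting exact packing on these
   instance sizes only tightens the guarantee, giving the 1.5 ratio (the ε
   never needs instantiating — `swap_radius` is the practical knob);
3. complete the matching: first all identical ghost-free left/right element
   pairs are committed as 2-cycles — an exchange argument shows rewiring
   any optimal decomposition through such a pair never loses a helpful
   cycle, and without this step exact 4-cycle packing can actively hurt
   (on identical single-gene linear genomes it would pack one 4-cycle where
   two 2-cycles are optimal and report distance 1 between identical
   genomes). The remaining slots are closed greedily into the **shortest
   available cycle** from the lowest open slot (breadth-first search with
   per-path slot tracking; a plain greedy walk is the fallback if the
   search fails). Shortest-first closure is what makes the pipeline exactly
   optimal on duplicate-free instances, where the only freedom left is how
   null extremities pair up;
4. count **all** helpful cycles of the completed decomposition (not just
   the packed ones), recover telomeres, and report the distance.

Recovery removes every matched τ-edge, drops the ττ padding and restores
`x·τ` caps to telomeres, splitting each affected cycle into paths. The
reported distance is computed from these **recovered components**
(d = n − c − o/2 with the uncapped n): for an optimally arranged capped
decomposition the two counts coincide, but a greedy capped decomposition
can route null extremities so that recovery yields strictly more value —
the recovered count is what the emitted scenario actually achieves, so it
is the honest (and never worse) figure.

## Scenarios

`build_scenario()` turns each recovered component into concrete rewrites,
processed deletions first, then insertions, then DCJs:

- each T₁ ghost consumes its two left neighbors (adjacencies or telomeres)
  through one of the four deletion schemas;
- each T₂ ghost is inserted so that it immediately splits off a matched
  2-cycle with one of its right neighbors; ghost chains are processed from
  a real anchor, a cycle consisting purely of ghosts is bootstrapped with a
  circular single-gene insertion, and a ghost flanked by right telomeres
  uses the two-telomere insertion schema;
- the all-real remainder is resolved by DCJs that split off one matched
  2-cycle each; paths are trimmed from a left-telomere end where possible
  (two edges per operation) — trimming from a right-telomere end removes
  only one edge and is used exactly once, on paths whose both endpoints are
  right telomeres.

The proof technique behind the cost accounting details ghost handling only
inside cycles; the package applies the same local rules on paths, which
preserves the stated path costs (this extension is exercised by the replay
tests). Per component the costs are: helpful cycle ℓ/2 − 1, unhelpful cycle
ℓ/2, odd path (ℓ−1)/2, even path ℓ/2; summed, exactly |T₁| deletions, |T₂|
insertions and distance-many operations overall. `verify_scenario()`
replays every operation against the rewrite schemas and checks the final
multiset — the test suites require a 100% replay rate.

## The simulator

`random_genome()` draws per-family copy numbers as 1 + Poisson(`copy_rate`)
(optionally capped), shuffles copies and orientations uniformly, and splits
them into chromosomes whose topology is circular with probability
`circular_fraction`. `apply_random_operations()` samples a history at the
adjacency-set level — the model's native domain, avoiding a second
definition of operation semantics on chromosomes — and realizes the result
back into a genome. Deletions only target existing copies; insertions
duplicate an existing family with probability ½, otherwise invent a fresh
label, so both ghost directions are exercised.

Simulated pairs carry a known history length *k*, hence oracle distance ≤ k
— an upper bound, not the truth, since random operations can cancel. What
passing the simulated suites does **not** show: real genomes have biased
rearrangement length distributions, hotspots, and segmental (multi-gene)
duplications; the model's single-gene indels and unit costs are deliberate
simplifications, so distances on real data should be read as lower-bound
style dissimilarities rather than event counts.

## Numerical and design choices

- **Determinism.** Element ordering (origin, canonical label pair, input
  position), candidate enumeration, packing tie-breaks, completion order and
  realization tie-breaks (grow linear chromosomes from the smallest unused
  telomere, consume the smallest matching occurrence) are all fixed, so
  identical inputs and seeds give byte-identical outputs.
- **Realization of ambiguous multisets** picks one consistent genome; the
  round-trip property (`genome_to_adjacency_set` after `realize_genome`
  reproduces the multiset) is the contract, uniqueness is not.
- **Validation posture.** `validate_decomposition` returns violation
  reports; internal invariant breaches (unbalanced labels, non-integer
  distances, count-law violations during scenario assembly) stop with an
  error, since they indicate bugs rather than bad input.
- **Problem sizes.** The bundled suites use 200 random duplicate-gene
  instances (≤ 6 families, copy number ≤ 3, histories 1–5) for the
  approximation-vs-oracle ratio, 1000 duplicate-free pairs for the classic
  cross-check against an independent direct cycle walk, and over 100 small
  telomere-bearing instances for the capping-invariance check. These sizes
  keep the oracle exhaustive yet fast; the approximation itself handles far
  larger genomes (its costs are the O(n⁴) candidate enumeration and the
  packing).

## Known limitations

- Exact distances are exponential-time and gated by `max_side`; above it
  only the 1.5-ratio approximation is available.
- Single-gene indels only: block insertions/deletions and segmental
  duplications are modeled as repeated unit operations, which overcounts
  them relative to models with block events.
- Unit costs only; length- or type-dependent operation costs are out of
  scope.
- The distance is adjacency-set-level; chromosome-structure ambiguity under
  duplication is inherent to the model.
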