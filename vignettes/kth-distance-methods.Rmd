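---
title: "The kth-distance between rooted phylogenetic networks: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The kth-distance between rooted phylogenetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knetdist)
```

## The objects and the relation

A rooted phylogenetic network is a finite DAG with one root, every node
reachable from it, and the out-degree-0 nodes (leaves) labelled bijectively
by taxa. Nodes of in-degree ≥ 2 are reticulate; they model hybridization,
recombination and horizontal transfer. `knetdist` compares two such networks
through a chain of equivalence relations on nodes:

* **Order 1** (child side): leaves are equivalent when they carry the same
  taxon label; internal nodes when their children can be paired so that
  matched children are order-1 equivalent.
* **Even orders** (parent side): `u ≡ᵏ v` iff `u ≡ᵏ⁻¹ v` and either both are
  roots or their parents pair under `≡ᵏ`.
* **Odd orders ≥ 3** (child side again): `u ≡ᵏ v` iff `u ≡ᵏ⁻¹ v` and either
  both are same-labelled leaves or their children pair under `≡ᵏ`.

The same clauses, read across two networks with label identity as the base
case, define cross-network equivalence on the disjoint union of the node
sets. From the per-order class sizes the kth-distance aggregates, for each
order, how much class mass on either side has no equally large partner class
on the other side, normalized by `k (n₁ + n₂)` (see the README for the
formula). All sums are integers; the package keeps the distance as an exact
reduced rational (`numerator`, `denominator`) next to its float rendering,
so statements like "the distance is exactly 16/21" and the triangle
inequality are testable without floating-point tolerance.

## Design choices where the construction is genuinely open

**Unordered neighbour lists.** The defining clauses ask for *some* pairing
of children (or parents) with equivalent mates. Since each order is an
equivalence relation, such a pairing exists iff the multisets of neighbour
class ids coincide; the implementation therefore assigns classes by
signature refinement (a Hopcroft-style partition chain) processing nodes in
increasing height for child-side orders and increasing depth for parent-side
orders, both well-founded because height strictly drops along edges and
depth strictly rises. This runs in `O(k·|E|·log|V|)`. Fidelity to the
flag-based pairwise recursion is not assumed: `naive_equivalent()` is a
direct memoized implementation of the definitions with exhaustive bipartite
matching, kept as an independent oracle, and the suite checks full agreement
on hundreds of seeded universes.

**Roots in two-network scope.** The even-order base clause "u, v are the
root" is read as "u is the root of its network and v is the root of its
network"; the reflexivity proof of the metric on reduced spaces requires
exactly this reading.

**One-node networks.** A single node is root and leaf at once; it satisfies
the leaf clause at odd orders (label must match) and the root clause at even
orders. Both are applied literally.

**Multi-edges.** Parallel edges are rejected. The edge set is treated as a
set; multiset edges would make "u has l children u₁…u_l" ambiguous.
In-degree-1/out-degree-1 nodes, by contrast, are accepted on input: the
reduction step is defined to remove them, so they must be representable.

**Reduction procedure.** Membership in the order-k reduced space ("every
node equivalent only to itself, no unary node") is the contract;
`reduce_network()` is one faithful procedure reaching it: per pass, merge
every non-singleton order-k class onto its lexicographically least node id
(classes are height-homogeneous, so merges cannot create cycles, and two
leaves of one network never share a class because labels are unique),
collapse duplicate edges, suppress unary nodes, repeat to fixpoint. The
representative choice only affects node naming, never the distance, which
consumes class sizes alone; a test asserts invariance under renaming.
Uniqueness of the reduced network up to isomorphism is not claimed.

**k = 0** is rejected; the chain starts at order 1.

## The synthetic data: what it emulates and what it does not

`random_network(n_leaves, n_reticulations, seed)` grows a uniform random
rooted binary tree by repeatedly joining two subtree roots, then adds
reticulation edges uniformly among pairs `(u, v)` with `depth(u) < depth(v)`,
`u` internal and `(u,v)` not yet an edge — a criterion that preserves
acyclicity and the single root by construction. `max_extra_depth` optionally
inserts pass-through (in-degree-1/out-degree-1) nodes on random edges; these
exist solely to exercise the suppression step. Defaults in the tests are
desk-scale (3–6 leaves, 0–2 reticulations), matching the sizes at which the
brute-force oracles are exact.

This generator emulates topological variety, not evolutionary realism: it
has no branch lengths, no explicit hybridization model, no taxon-sampling
process, and its reticulation density is uniform rather than clustered. A
green property suite therefore establishes the combinatorial claims (metric
axioms on the tested orders, oracle agreement, reduction postconditions) on
this stated world — it does not certify behaviour on networks produced by
any particular reconstruction method, and no published benchmark
distribution is reproduced here.

The figure fixtures under `inst/extdata/` are **synthetic reconstructions**:
the drawings they transcribe are not machine-readable, so each network was
re-derived from the checkable facts stated about it (named equivalence
pairs, node counts, taxon sets, named unpaired order-1 representatives,
non-isomorphism). `load_fixture()` re-verifies every fact at load time and
refuses a drifted transcription. Two of the published fact sets required a
decision:

* For the 13/15-node pair, the stated attachment of the unpaired node sets
  (five to the 13-node network, three to the 15-node one) is arithmetically
  impossible: it forces paired class mass 8 on one side against 12 on the
  other, making the order-1 discordance at least 12, not the printed 8. The
  attachment is therefore swapped (three unpaired of 13, five of 15), which
  reproduces the printed sum `S₁ = 8` and distance `16/21` exactly and
  matches the structure of the companion unequal-taxon example, which is
  consistent as printed.
* For the first figure pair, the printed claims "the formula evaluates to 0
  at k = 1 and k = 2" and "at order 3 the discordance equals n₁ + n₂" are
  mutually unsatisfiable for *any* pair of networks: taxon labels are unique
  within a network, so a perfect order-2 comparison pairs every shared-label
  leaf pair, the odd-order leaf clause then keeps those pairs at order 3,
  and height-1 nodes (whose children are exactly those leaves) follow; hence
  `S₃ ≤ n₁ + n₂ − 2(|X| + #height-1 nodes) < n₁ + n₂` whenever
  `S₁ = S₂ = 0`. The reconstruction honours the lower-order facts and the
  within-network equivalence facts; its order-3 distance is 1/9 (the maximum
  its shape admits), not 1/3, and the corresponding acceptance check is left
  failing by design rather than weakened.

## Numerical and procedural details

* **Exact arithmetic.** Per-order sums are integers; distances are reduced
  rationals; the triangle inequality is checked by integer
  cross-multiplication. All magnitudes at desk scale stay far below the
  exact-integer range of doubles.
* **Determinism.** Canonical eNewick output sorts children by the sorted
  taxon set below them (ties by node id) and numbers `#H` tags in traversal
  order; representative choice and all sorting use radix (C-locale) order;
  the generator restores the session RNG state.
* **Short-circuit.** Once a partition is discrete, higher orders reuse it —
  refinement cannot coarsen. The same monotonicity yields `S_i ≤ S_{i+1}`
  (each split of a paired class can only expose more unpaired mass), which
  the suite asserts as non-strict.
* **Degenerate inputs.** One-node networks, networks with reticulate leaves,
  non-binary nodes of any arity, and pairs with disjoint or nested taxon
  sets all flow through the same code paths; no special-casing beyond the
  two base clauses.

## Known limitations

* **Distance 0 does not imply isomorphism outside the reduced space** (the
  shared-parents/shared-children fixture `fig7_n` is the canonical obstacle),
  and pairs of non-isomorphic networks with distance 0 at *every* order
  exist; no such pair is shipped because its published topology is not
  recoverable, so this blind spot is documented rather than tested on that
  exact pair.
* **The triangle inequality can fail at k = 1 on the full space**, even
  between first-order *reduced* networks of very different sizes: with
  N₁, N₂ the cherries on {1,2} and {3,4} and N₃ the 7-node network joining
  both cherries under one root, `d₁(N₁,N₃) = d₁(N₂,N₃) = 4/10` but
  `d₁(N₁,N₂) = 1`. The root-anchored even orders block this construction for
  k ≥ 2. The property suite tests the axioms on same-taxon-set triples at
  k = 3, where they hold exactly; cross-size comparisons at k = 1 should be
  interpreted with care.
* The naive equivalence and isomorphism oracles are exponential and bounded
  at 16 nodes per network; they are test instruments, not user-facing
  features.
* The metric is purely topological and leaf-labelled: no branch lengths,
  no edge weights, no support values.
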