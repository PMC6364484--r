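---
title: "Incremental quartet-voting phylogeny estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental quartet-voting phylogeny estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inctree)
```

## The estimation problem

`inctree` estimates an unrooted binary tree topology on $n$ taxa from a
dissimilarity matrix $d$, usually computed from a multiple sequence
alignment.  The statistical backdrop is the classical one: sequences evolve
i.i.d. across sites along an unknown model tree $T$ whose edges $e$ carry
weights $w(e) \in [f, g]$ (expected substitutions per site), and the
empirical distances $d_{ij}$ converge to the additive matrix
$D_{ij} = \sum_{e \in P_{ij}} w(e)$ of path sums.  Two distance estimators
are provided:

* **Two-state (CFN) distances.** For binary data under the symmetric
  two-state model, $d_{ij} = -\tfrac12 \ln(1 - 2H_{ij})$, where $H_{ij}$ is
  the normalized Hamming distance.  Pairs with $H_{ij} \ge \tfrac12$ are
  *saturated*: the transform is undefined and the entry is recorded as the
  finite sentinel `MAX_DIST` ($10^6$).
* **Log-det distances.** For $m$-state data under any general Markov model
  (including general time reversible models),
  $d_{ij} = -\log\det \hat F_{ij}$, where $\hat F_{ij}$ is the $m \times m$
  relative-frequency matrix of joint site patterns.  A non-positive
  determinant saturates the pair.  Log-det distances are additive only up
  to a constant shift of all off-diagonal entries; the package deliberately
  does **not** correct the shift, because every consumer of the matrix is
  shift-invariant — the four point comparison shifts both pairing sums by
  the same $2c$, and the spanning-tree bottleneck weight that calibrates
  the validity radius shifts along with the quartet diameters.

## The insertion algorithm

The core estimator adds taxa one at a time to a growing tree $t$:

1. **Ordering.** Build a minimum spanning tree $S$ of the complete distance
   graph.  Let $q_0$ be the heaviest edge of $S$ — equivalently the
   smallest threshold at which the distance graph is connected — and set
   the validity radius $q = 8 q_0$.  Order the taxa by BFS over $S$ from a
   leaf, so that every prefix of the ordering is connected in $S$.
2. **Queries.** Every internal node $u$ of $t$ stores a triple of leaves
   $u_1, u_2, u_3$, one from each component of $t - u$, each witnessed by
   an $S$-edge leaving its component (prefix connectivity guarantees such
   witnesses exist).  When inserting taxon $x$, the quartet
   $\{u_1, u_2, u_3, x\}$ is *valid* if its $d$-diameter is strictly below
   $q$; valid queries are resolved by the four point method and vote for
   every edge of the component paired with $x$ (plus its connecting edge).
3. **Tally.** Vote counts of adjacent edges sharing node $u$ differ only
   through $u$'s own query, by $\{-1, 0, +1\}$, so one BFS from a leaf
   recovers all counts in linear time; the anchor edge's absolute count is
   obtained directly.  The top-voted edge is subdivided and $x$ attached;
   ties are broken by a seeded uniform draw.

The radius balances two failure modes: too small and correct quartets
cannot cover the tree, too large and long-distance quartets become
unreliable.  The multiplier 8 follows the method's correctness analysis and
is exposed as a tunable (`inc_config(q_mult = )`) since nothing suggests it
is optimal.

Exact recovery holds whenever the short-range error
$\epsilon(q) = \max\{|d_{ij} - D_{ij}| : d_{ij} \le q$ or $D_{ij} \le q\}$
is below $f/2$ (with $f$ the shortest internal edge weight) — in
particular for additive inputs — and the test suite exercises both
regimes directly.

## Constrained insertion and divide and conquer

`constrained_inc_build()` accepts leaf-disjoint constraint trees that the
output must induce exactly.  When inserting $x$, its constraint tree
$t_c$ is restricted to the leaves $A$ already placed; reading off where
$x$ attaches in $t_c^{A \cup \{x\}}$ identifies one edge of the induced
topology $t^A$, and the vote argmax is restricted to the corresponding
*component* of the growing tree (the contracted path plus its hanging
subtrees).  Votes are still tallied over the whole tree — the
differential tally is linear anyway — and then masked, which is
equivalent to running the insertion on the component alone.

`inc_nj_build()` uses this machinery for divide and conquer: the taxa are
partitioned by greedy ball-growing in the threshold graph (balls of at
most $\lceil\sqrt n\rceil$ taxa within radius $q$ of a seed), neighbor
joining is run on each ball, and the resulting subset trees become the
constraints.  Balls of fewer than 3 taxa constrain nothing and their taxa
are placed by ordinary voting.  At `cap = n` (one ball, when the radius
covers all taxa) the pipeline degenerates to neighbor joining; at
`cap = 1` it degenerates to unconstrained insertion — both degeneracies
are tested.  The description of the decomposition leaves seed choice,
within-ball ordering and leftover handling open; the package fixes them
deterministically (lexicographically smallest unassigned seed, ascending
distance then label, singletons pass through).  A ball within radius $q$
need not be a clique of the threshold graph; no pairwise closeness check
is performed.

## The synthetic-data generators

All test inputs are generated in code:

* `random_model_tree(n, f, g)` draws a uniform random binary topology
  (sequential attachment to a uniformly chosen edge) with
  $w(e) \sim \mathrm{Uniform}[f, g]$, exercising the boundaries of the
  model class, and $p(e) = (1 - e^{-2w(e)})/2$.
* `evolve_cfn()` propagates equiprobable root states with per-edge flip
  probability $p(e)$, i.i.d. across sites.
* `random_gtr_model(n, f, g, m)` samples a stationary distribution from a
  symmetric Dirichlet (concentration 5, floored at 0.05 and renormalized
  so no state is vanishingly rare), Uniform(0.5, 2) exchangeabilities, and
  calibrates each edge duration through the exact identity
  $-\log\det e^{\tau Q} = -\tau\,\mathrm{tr}(Q)$, so every edge's log-det
  weight lands in $[f, g]$ with no numerical search.
* `perturb_distances()` adds bounded symmetric uniform noise to an
  additive matrix, the adversarial-error model under which recovery is
  guaranteed while the bound stays below $f/2$.

What the generators deliberately do **not** emulate: among-site rate
variation, indels and alignment error, base-composition drift, and any
correlation between sites.  Passing tests therefore demonstrate
correctness of the algorithms under their stated assumptions, not
robustness of the estimators to real-data violations of those
assumptions.

Each generator wraps a single integer seed around a fixed traversal
order (`withr::with_seed`), which makes every artifact reproducible from
its seed; sub-seeds for batches are always drawn from one parent stream
rather than taken as consecutive integers, which would bias the first
categorical draw after reseeding.

## Numerical and degenerate-input choices

* **Saturation.** Saturated pairs carry the finite sentinel rather than
  `Inf` so spanning trees remain computable; a sentinel edge forced into
  the spanning tree demotes $q_0$ to the heaviest finite edge (with a
  warning) instead of making every quartet trivially valid.  Saturated
  quartets never vote, and `neighbor_joining()` rejects saturated input
  outright.
* **Ties.** The four point method breaks exact ties toward the
  lexicographically smallest split and flags them; vote-count ties are
  broken by a seeded uniform draw; spanning-tree and BFS ties are broken
  by labels.  Equal runs are therefore byte-identical.
* **Validity is strict** (`diameter < q`), matching the definition the
  correctness argument uses.
* **Zero valid queries.** Possible on real data outside the guaranteed
  regime.  The builder then doubles the radius (up to 10 times), finally
  forcing all queries, and reports the events in the run's statistics;
  the fallback cannot fire when the error bound $\epsilon(q) < f/2$
  holds.
* **Small inputs.** Fewer than 3 taxa return the trivial topology; the
  3-taxon star is built without queries since only one topology exists.
* **Log-det diagonal** is stored as 0 (the estimator's
  $-\log\det\hat F_{ii}$ is positive but unread).

## Problem sizes in the test suite

The suite verifies exact recovery on 100 instances of 10–100 leaves,
bounded-noise recovery on the same instances, neighbor joining and the
divide-and-conquer pipeline on 50 instances each (up to 100 leaves), the
differential tally against brute-force counting on 200 instances, and
sequence-length sweeps (20 replicates, 30 leaves,
$k \in \{500, 5000, 50000\}$ sites) for both the two-state and the
log-det/GTR pipelines.  These sizes keep a full run to a few minutes
while covering every guarantee at the scale where independent oracles
(split enumeration, explicit vote counting, external tree libraries) are
cheap to evaluate.

## Known limitations

* Purely topological output: branch lengths are carried through I/O but
  never estimated.
* No handling of missing data beyond saturation, and no distance-variance
  weighting.
* Constraint trees must be leaf-disjoint; overlapping constraint sets are
  rejected rather than reconciled.
* The constrained variant trusts its constraints: a wrong constraint tree
  is faithfully induced in the output.
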