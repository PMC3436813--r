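---
title: "Reconciliation with duplication, transfer, loss and lineage sorting: the model behind dtli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciliation with duplication, transfer, loss and lineage sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtli)
```

## The problem

A gene family evolving strictly by vertical descent produces a gene tree
congruent with its species tree.  Four processes break that congruence:
gene **duplication** (D), **horizontal transfer** (T), gene **loss** (L)
and **incomplete lineage sorting** (I, also called deep coalescence) —
the survival of allelic variation across rapid successive speciations.
`dtli` reconciles a rooted binary gene tree with a rooted species tree
under a parsimony criterion covering all four processes.  Regions of the
species tree where lineage sorting is plausible are marked by polytomies:
at a binary species node, incongruence is always evidence of duplication
or transfer; at a polytomy, branching patterns that match *some* binary
resolution of the polytomy are attributed to lineage sorting at no cost.
Users with a fully resolved species tree can collapse short or poorly
supported edges (`collapse_edge()`) to enable the lineage-sorting
interpretation exactly where they suspect it.

## The score and the event test

A reconciliation annotates every internal gene node `g` with a species
`M(g)` and an event, and every gene edge with the losses implied along
it.  Its score is

> score = delta * n_D + tau * n_T + lambda * n_L

with speciation and deep coalescence free.  Defaults are `dup = 3`,
`loss = 2`; the transfer weight has no natural default and must be given.
The DT and DTI model variants drop the loss term from the objective (but
still reconstruct losses for reporting); the variants without I insist on
a binary species tree.

Whether the divergence at `g` is a duplication is decided by an
inheritance-overlap test: for each child of `g`, compute the set of
children of `M(g)` that *vertically* inherit one of its descendants
(lineages reached only through a transfer edge are excluded).  If the two
sets overlap, some lineage carries two copies and the divergence must be
a duplication.  If they are disjoint, the event is a transfer when one
child is mapped to a lineage incomparable to `M(g)` (that child edge is
the horizontal edge, donor `M(g)`, recipient the child's species), and
otherwise a co-divergence: a speciation at a binary node, a deep
coalescence at a polytomy.  On binary species trees this test reduces to
classical lca reconciliation.

Because a gene node mapped to a polytomy may pass its descendants to any
nonempty subset of the polytomy's children, the dynamic program indexes
its per-node tables by the pair `(s, sigma)` where `sigma` ranges over
nonempty child subsets.  Table size therefore grows as `2^k` in the
largest out-degree `k`; the method is intended for small polytomies
(out-degree up to about 6) and `build_species_index()` refuses trees with
`k > 12` unless forced.

## The loss heuristic

Losses on a gene edge are reconstructed by walking the species-tree path
from the parent's context down to the child's assignment:

* every binary species node passed with its other child uninvolved
  contributes one loss in that sibling lineage;
* a polytomy passed or terminated in with incomplete child coverage
  contributes exactly **one** loss, labelled with the whole uncovered
  child set — any uncovered subset can form a clade in some binary
  resolution and be lost as a single unit.

The starting point of the walk depends on the parent event.  A
co-divergence distributes copies directly into child lineages of `M(g)`,
so the walk starts below `M(g)`; in particular a co-divergence child that
stays at the same polytomy covers exactly the lineages it entered and is
charged nothing — this is precisely what makes every gene tree congruent
with a binary resolution cost zero, and it is enforced by a property test
over hundreds of simulated resolutions.  A duplication copy, and the
vertically inherited child of a transfer, must themselves traverse the
divergence at `M(g)`, so their walk includes it.  A horizontally
transferred child is charged only for incomplete coverage at the
recipient.

The end of the walk is symmetric: incomplete coverage at the child's own
node is charged on the incoming edge only when the child's event is a
co-divergence there.  A duplication or transfer at the child happens on
the branch above its node, before the radiation, and its copies pay for
crossing it on their own outgoing edges — charging the incoming edge too
would double-count (this is the polytomy generalisation of the classical
binary rule in which an edge's loss count is the path length corrected
by the duplication status of its endpoints).  Because a parent must
price co-divergence and non-co-divergence children differently, the
dynamic-program tables are keyed by `(s, sigma, is_codivergence)`.

### A consequence worth knowing

For the textbook four-taxon instance — gene tree `((A,B),(C,D))` against
species tree `(A,(B,C,D))` — two explanations are often pictured: a
duplication followed by three losses (cost `dup + 3*loss`), or a
transfer between `A` and `B` with one loss (cost `trans + loss`).  Under
the model as specified there is a third, cheaper explanation: the root
coalesces at the polytomy, sorting `{B}` against `{C,D}`, and the
`(A,B)` ancestor, resident in lineage `B`, donates a copy to `A` — one
transfer, no losses, cost `trans`.  Charging that history an extra loss
would require also charging the identical local configuration that makes
resolution-congruent trees free, so `dtli` accepts it: at `trans = 7`,
`dup = 3`, `loss = 2` the optimum is 7 with a single history, and the
classical duplication-vs-transfer tie appears at `trans = dup + 3*loss`
instead:

```{r worked}
sols <- reconcile("((A,B),(C,D));", "(A,(B,C,D));",
                  data.frame(gene = LETTERS[1:4], species = LETTERS[1:4]),
                  cost_scheme(dup = 3, loss = 2, trans = 9))
tidy(sols)
```

## All optimal histories, and why they matter

With transfers in the model the optimum is rarely unique, and different
optima can tell incompatible stories.  The first pass fills cost and
history tables in one post-order sweep, keeping *every* tied candidate;
the traceback (`second_pass()`) then emits each optimal history exactly
once.  A history is identified by the species assignment of every gene
node — the assignment determines the inheritance sets, events, transfer
edges and loss records, a fact the test suite exploits by comparing the
enumerated set against an independent brute-force enumerator of
assignment vectors.  Enumeration is capped (`max_histories`, default
10000) with an explicit truncation flag; the optimal count itself is
always exact.  A solution set whose histories disagree in any event
count is flagged *degenerate*; batch aggregation excludes such trees, on
the view that a randomly chosen optimum would be misleading.

## Temporal feasibility

Each transfer requires donor and recipient lineages to have coexisted.
Feasibility of a history is decided by building a directed "predates"
graph over the species involved in transfers and testing it for cycles
(`build_timing_graph()`, `is_temporally_feasible()`).  Three constraint
classes are encoded: strict species-tree ancestry; ordering between
transfers on comparable gene lineages (applied reflexively, which also
encodes that each transfer happened while both of its lineages existed);
and contemporaneity propagation — whatever strictly predates one side of
a transfer predates the other — iterated to a fixpoint.  Design choices
here: ancestry and contemporaneity use *strict* ancestry (a reflexive
reading would make every single transfer trivially cyclic); parents of
donors and recipients referenced by the ordering constraints are added
to the graph's vertex set; a root donor degrades to the root itself.
Histories are screened after enumeration; when every optimum fails the
screen the solution set is returned with status
`all_optimal_infeasible` — searching for an optimal *feasible* history
in that situation is a much harder problem and is out of scope.

## Batch analysis, rooting, highways

`batch_reconcile()` sweeps a tree collection over model variants and
transfer costs, applying the standard retention protocol: per cell, drop
trees with no feasible optimum (infeasible) and trees with conflicting
optimal counts (degenerate); under the default `cross_model` policy a
tree infeasible anywhere is dropped everywhere, which keeps cells
comparable.  `root_search()` reroots a gene tree on every edge and
reconciles each rooting, returning all minimum-score roots.
`transfer_matrix()` folds donor→recipient and recipient→donor counts
into unordered species-pair totals (internal lineages keyed by node
name), and `detect_highways()` flags pairs whose total strictly exceeds
the mean by 1.5 population standard deviations, both moments taken over
*all* unordered pair counts including zeros (the SD convention is a
package choice; the multiplier is a parameter).

## The simulator

`simulate_history()` plants a known history: a single lineage enters at
the species root; on each species edge it draws Poisson numbers of
duplications, transfers and losses (expectations `r_dup`, `r_trans`,
`r_loss` per lineage per edge, applied in random order; a fresh draw is
made for each newly created copy); transfers pick a uniformly random
incomparable lineage; at a polytomy each crossing lineage sorts through
its own uniformly drawn binary resolution (`ils = "hard"`; a shared
resolution per polytomy is available as `"soft"`).  Extinct or
single-copy outcomes are returned as an `extinct` marker for the caller
to retry.  The planted event counts give an upper bound on the optimal
score, asserted as a property test.  What the simulator does *not*
emulate: branch lengths and population sizes (so ILS frequency is not
calibrated to a coalescent), sequence evolution, replacement transfers,
and multi-gene transfer events — conclusions from passing tests carry
over to real data only at the level of the combinatorial model.

## Numerical and engineering choices

Scores are doubles; ties are recognised with an absolute epsilon of
1e-9 (test fixtures use half-integer weights so ties are exact).
Inheritance subsets are integer bitmasks over a node's children; node
ids are assigned in deterministic post-order, and candidate enumeration
is sorted, so outputs are bit-stable across runs.  Invalid candidates
(a child mapped above its parent's species, or both children horizontal)
are simply never tabulated, which plays the role of an infinite-cost
sentinel.  The exhaustive oracle is guarded to at most 6 gene leaves and
11 species nodes; the order-search feasibility oracle to 8 graph
vertices.  The test suite sizes its random instances accordingly
(species trees of 3–8 leaves, gene trees of 3–8 leaves, 200-instance
equivalence batteries, 500-instance lineage-sorting sweeps), which keeps
the whole suite to a few minutes while still exercising every branch of
the candidate space.

## Known limitations

* Collapsing a species edge is **not** guaranteed to lower the optimal
  score once transfers are in the model.  Lineage sorting can only help,
  and duplication/loss histories survive the collapse, but a transfer
  whose donor is the collapsed node loses its donor lineage, and a
  transfer between a node and a relative inside the enlarged polytomy
  can become donor-comparable-to-recipient and hence invalid; the
  cheapest replacement history can cost strictly more.  (Verified
  against the exhaustive enumerator on small instances; transfer-free
  optima do behave monotonically.)
* When all optima are temporally infeasible, no feasible suboptimal
  history is searched for.
* Transfers move one gene at a time; multi-gene transfer events and
  extinct/unsampled donor species are not modelled.
* The parsimony criterion ignores branch lengths; where population
  parameters are available, coalescent-based methods can discriminate
  histories this model cannot.
* Event weights are user choices; conclusions should be checked across a
  grid of transfer costs (as `batch_reconcile()` encourages).
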