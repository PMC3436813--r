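# dtli

Reconciliation of rooted binary gene trees with rooted, possibly
non-binary species trees under a **D**uplication / **T**ransfer /
**L**oss / **I**ncomplete-lineage-sorting parsimony model, for
phylogeneticists studying gene-family evolution in clades where both
horizontal transfer and rapid radiations (hence deep coalescence) are in
play — prokaryotic pan-genomes, rapidly diverging eukaryote groups, and
any dataset where short species-tree edges make binary branching orders
untrustworthy.

## The model

A reconciliation maps every internal gene-tree node `g` to a species
`M(g)` and an event, and charges

```
score = δ·(duplications) + τ·(transfers) + λ·(losses)
```

with speciation and deep coalescence free.  At binary species nodes,
incongruence is evidence of duplication or transfer; at polytomies, any
gene-tree branching consistent with *some* binary resolution is
attributed to lineage sorting at zero cost.  The duplication test is an
inheritance-overlap test on the sets of species-children that vertically
inherit each gene child's descendants (transfer-acquired leaves
excluded); when those sets are disjoint the event is a transfer (one
child in a lineage incomparable to `M(g)`) or a co-divergence.  On
binary species trees this reduces to classical lca reconciliation.

A two-pass dynamic program (post-order table fill, pre-order traceback)
returns **all** minimum-cost histories, each annotated with per-node
events, per-edge loss records and transfer donor/recipient pairs.  Each
history is then screened for temporal feasibility: its transfers imply
"predates" constraints among species, and the history is kept iff the
constraint graph is acyclic.  Batch utilities sweep tree collections
over the four model variants (DT, DTI, DTL, DTLI) and transfer-cost
grids, root trees by event parsimony, tabulate per-lineage event counts,
and flag transfer "highways" — species pairs whose bidirectional
transfer totals exceed the mean by 1.5 standard deviations.

See `vignettes/dtli-methods.Rmd` for the full account, including the
loss heuristic at polytomies and the timing-graph constraint classes.

## Worked example

Gene tree `((A,B),(C,D))` against species tree `(A,(B,C,D))`, whose
`(B,C,D)` clade is a polytomy, with δ = 3, λ = 2, τ = 9:

```r
library(dtli)
sols <- reconcile("((A,B),(C,D));", "(A,(B,C,D));",
                  data.frame(gene = LETTERS[1:4], species = LETTERS[1:4]),
                  cost_scheme(dup = 3, loss = 2, trans = 9))
sols
#> <dtli_solutions model=DTLI  score 9, 2 optimal histories (2 enumerated)>
tidy(sols)
#> # A tibble: 2 × 8
#>   history score n_dup n_trans n_loss n_coal n_spec feasible
#>     <int> <dbl> <int>   <int>  <int>  <int>  <int> <lgl>
#> 1       1     9     0       1      0      2      0 TRUE
#> 2       2     9     1       0      3      1      1 TRUE
```

Two optimal, temporally feasible explanations tie at score 9: a single
transfer out of the sorted `B` lineage into `A` (two deep coalescences,
no losses), or a duplication below the root followed by three losses.
The solution set is flagged *degenerate* (`glance(sols)$degenerate`)
because the optima disagree in their event counts — exactly the
situation in which picking one optimum arbitrarily would mislead.
At cheaper transfer costs (e.g. τ = 7) the transfer history alone is
optimal at score 7; at τ = 10 the duplication history wins at 9.

Annotated output for any history:

```r
write_annotated_tree(sols$histories[[2]], "example")  # .nhx + .events.tsv
```

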