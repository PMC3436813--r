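test_that("event classification follows the inheritance-overlap test", {
  fx <- fig_instance(); idx <- fx$index
  # children split cleanly at the binary root -> speciation
  expect_equal(classify_event(idx, "A+B+C+D", "A", "B+C+D"), "speciation")
  # both children inherit through the polytomy lineage -> duplication
  expect_equal(classify_event(idx, "A+B+C+D", "B+C+D", "B+C+D"),
               "duplication")
  # disjoint child subsets at the polytomy -> deep coalescence
  expect_equal(classify_event(idx, "B+C+D", "B+C+D", "B+C+D",
                              sigma1 = c("B", "D"), sigma2 = "C"),
               "coalescence")
  # one child incomparable to the node -> transfer
  expect_equal(classify_event(idx, "A", "A", "B"), "transfer")
  # both children incomparable -> no consistent event
  expect_equal(classify_event(idx, "B", "A", "A"), "invalid")
  # duplication at a species leaf (paralogs)
  expect_equal(classify_event(idx, "A", "A", "A"), "duplication")
})

test_that("inherited lineages implement the sigma set", {
  fx <- fig_instance(); idx <- fx$index
  # child strictly below: the child of s on the path
  expect_equal(inherited_lineages(idx, "A+B+C+D", "B"), "B+C+D")
  # child at the same polytomy: its own sigma set
  expect_setequal(inherited_lineages(idx, "B+C+D", "B+C+D",
                                     sigma_child = c("C", "D")),
                  c("C", "D"))
  # horizontal child inherits nothing vertically
  expect_length(inherited_lineages(idx, "A", "B"), 0)
  # species leaf: the distinguished self marker
  expect_equal(inherited_lineages(idx, "A", "A"), "A")
  expect_error(inherited_lineages(idx, "B", "B+C+D"), "above")
})

test_that("loss records follow the bypass/uncovered-clade rule", {
  fx <- fig_instance(); idx <- fx$index
  # duplication copy descending from the root to the polytomy, surviving
  # in C and D: bypasses lineage A, leaves the B clade uncovered
  rec <- count_losses(idx, "duplication", "A+B+C+D", "B+C+D",
                      sigma_child = c("C", "D"))
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$label, c("A", "B"))
  # lineage entering the polytomy and surviving only in B: one clade loss
  rec2 <- count_losses(idx, "speciation", "A+B+C+D", "B")
  expect_equal(nrow(rec2), 1)
  expect_equal(rec2$label, "C,D")
  expect_equal(rec2$kind, "clade")
  # child at the same species with full coverage: nothing bypassed
  rec3 <- count_losses(idx, "duplication", "A+B+C+D", "A+B+C+D")
  expect_equal(nrow(rec3), 0)
  # a coalescence child entering a subset of the polytomy is the
  # lineage-sorting pattern, not a loss
  rec4 <- count_losses(idx, "coalescence", "B+C+D", "B+C+D",
                       sigma_child = c("C", "D"))
  expect_equal(nrow(rec4), 0)
  # horizontal child charged only at the recipient
  rec5 <- count_losses(idx, "transfer", "A", "B+C+D",
                       sigma_child = "C", horizontal = TRUE)
  expect_equal(nrow(rec5), 1)
  expect_equal(rec5$label, "B,D")
})

test_that("candidate scores combine event, child and loss terms", {
  cs <- cost_scheme(dup = 3, loss = 2, trans = 7)
  expect_equal(candidate_cost("speciation", c(0, 0), c(0, 0), cs), 0)
  expect_equal(candidate_cost("duplication", c(0, 0), c(1, 2), cs), 9)
  cs2 <- cost_scheme(dup = 3, loss = 2, trans = 2.5)
  expect_equal(candidate_cost("transfer", c(0, 0), c(1, 0), cs2), 4.5)
  expect_equal(candidate_cost("transfer", c(0, 0), c(1, 0), cs2,
                              losses_in_score = FALSE), 2.5)
  expect_error(cost_scheme(dup = 3, loss = 2), "trans")
})

test_that("congruent instances reconcile at score zero", {
  # gene tree identical to a binary species tree
  tg <- parse_newick("((a,b),(c,d));", "gene")
  ts <- parse_newick("((a,b),(c,d));", "species")
  mp <- read_leaf_mapping(
    data.frame(gene = letters[1:4], species = letters[1:4]), tg, ts)
  for (model in c("DT", "DTI", "DTL", "DTLI")) {
    dp <- first_pass(tg, ts, mp, cost_scheme(3, 2, 7), model)
    expect_equal(dp$score, 0)
    expect_equal(dp$n_histories, 1)
    sols <- second_pass(dp)
    expect_true(all(sols$histories[[1]]$nodes$event %in%
                      c("speciation", NA)))
  }
  # gene tree equal to one binary resolution of the polytomy
  fx <- fig_instance()
  tg2 <- parse_newick("(A,((B,D),C));", "gene")
  mp2 <- read_leaf_mapping(attr(fx$map, "table"), tg2, fx$ts)
  dp2 <- first_pass(tg2, fx$index, mp2, cost_scheme(3, 2, 7), "DTLI")
  expect_equal(dp2$score, 0)
  sols2 <- second_pass(dp2)
  ev <- unlist(lapply(sols2$histories, function(h) h$nodes$event))
  expect_true(all(ev %in% c("speciation", "coalescence", NA)))
})

test_that("the four-taxon worked instance matches the oracle landscape", {
  fx <- fig_instance()
  # tau = 10: the duplication history (3 losses) is the unique optimum
  dp10 <- first_pass(fx$tg, fx$index, fx$map, cost_scheme(3, 2, 10))
  expect_equal(dp10$score, 9)
  expect_equal(dp10$n_histories, 1)
  s10 <- summarize_events(second_pass(dp10))
  expect_equal(s10$counts$n_dup, 1)
  expect_equal(s10$counts$n_loss, 3)
  # cheap transfers: a single transfer out of the sorted B lineage
  # explains the tree without any loss
  dp7 <- first_pass(fx$tg, fx$index, fx$map, cost_scheme(3, 2, 7))
  expect_equal(dp7$score, 7)
  expect_equal(dp7$n_histories, 1)
  s7 <- summarize_events(second_pass(dp7))
  expect_equal(s7$counts$n_trans, 1)
  expect_equal(s7$counts$n_loss, 0)
  # both verified against exhaustive enumeration
  for (tau in c(2.5, 7, 10)) {
    cs <- cost_scheme(3, 2, tau)
    dp <- first_pass(fx$tg, fx$index, fx$map, cs)
    bf <- brute_force_reconcile(fx$tg, fx$index, fx$map, cs)
    expect_equal(dp$score, bf$score)
    expect_equal(dp$n_histories, bf$n_histories)
  }
})

test_that("models without I reject polytomies; tie at tau = dup + 3 loss", {
  fx <- fig_instance()
  expect_error(first_pass(fx$tg, fx$index, fx$map, cost_scheme(3, 2, 7),
                          "DTL"), "I-variant")
  expect_error(first_pass(fx$tg, fx$index, fx$map, cost_scheme(3, 2, 7),
                          "DT"), "I-variant")
  # at tau = 9 the duplication and zero-loss transfer histories tie
  dp9 <- first_pass(fx$tg, fx$index, fx$map, cost_scheme(3, 2, 9))
  expect_equal(dp9$score, 9)
  expect_equal(dp9$n_histories, 2)
  cnt <- summarize_events(filter_feasible(second_pass(dp9)))$counts
  expect_setequal(paste(cnt$n_dup, cnt$n_trans, cnt$n_loss),
                  c("1 0 3", "0 1 0"))
})

test_that("binary species trees reduce to classical lca reconciliation", {
  set.seed(31)
  for (i in 1:12) {
    ts <- random_species_tree(sample(3:6, 1))
    idx <- build_species_index(ts)
    ph <- simulate_history(sim_config(ts), seed = 600 + i)
    tg <- ph$gene_tree
    mp <- read_leaf_mapping(ph$map, tg, ts)
    dp <- first_pass(tg, idx, mp, cost_scheme(3, 2, 7), "DTL")
    expect_equal(dp$score, 0)
    h <- second_pass(dp)$histories[[1]]
    # independent lca mapping from the index
    for (g in which(!tg$is_leaf)) {
      tips <- which(tg$is_leaf & descends_from(tg, g))
      lca <- Reduce(function(u, v) idx$lca[u, v], mp[tips])
      expect_equal(h$M[g], lca)
    }
    expect_true(all(h$nodes$event %in% c("speciation", NA)))
  }
})

test_that("relabeling species and gene leaves leaves the score unchanged", {
  set.seed(32)
  for (i in 1:8) {
    inst <- random_instance()
    cs <- random_costs()
    model <- if (inst$has_polytomy) "DTLI" else "DTL"
    s1 <- first_pass(inst$tg, inst$index, inst$map, cs, model)$score
    # permute species leaf labels via a bijection
    perm <- function(x) chartr("abcdefghij", "qrstuvwxyz",
                               chartr("0123456789", "abcdefghij", x))
    ts2 <- inst$ts; ts2$label <- ifelse(is.na(ts2$label), NA,
                                        perm(ts2$label))
    tg2 <- inst$tg
    tbl <- attr(inst$map, "table")
    mp2 <- read_leaf_mapping(
      data.frame(gene = tbl$gene, species = perm(tbl$species)), tg2, ts2)
    s2 <- first_pass(tg2, ts2, mp2, cs, model)$score
    expect_equal(s2, s1)
  }
})
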