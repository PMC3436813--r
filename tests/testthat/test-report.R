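test_that("event-parsimony rooting recovers the congruent root", {
  ts <- parse_newick("((a,b),(c,d));", "species")
  tg <- parse_newick("(((a,b),c),d);", "gene")  # misrooted congruent tree
  mp <- data.frame(gene = letters[1:4], species = letters[1:4])
  rs <- root_search(tg, ts, mp, cost_scheme(3, 2, 7), "DTL")
  expect_equal(min(rs$table$score), 0)
  best <- rs$table$newick[rs$table$best]
  roundtrip <- function(x) write_newick(parse_newick(x, "gene"))
  expect_true(any(vapply(best, roundtrip, "") ==
                    "((a,b),(c,d));" |
                  vapply(best, roundtrip, "") == "((c,d),(a,b));"))
  # a 3-leaf tree has exactly 3 candidate rootings
  rs3 <- root_search(parse_newick("((a,b),c);", "gene"),
                     parse_newick("((a,b),c);", "species"),
                     data.frame(gene = c("a", "b", "c"),
                                species = c("a", "b", "c")),
                     cost_scheme(3, 2, 7), "DTL")
  expect_equal(nrow(rs3$table), 3)
  # all-paralog family: every rooting implies the same three
  # duplications, so all five rootings tie
  tsym <- parse_newick("((a1,a2),(a3,a4));", "gene")
  ssym <- parse_newick("(a,b);", "species")
  msym <- data.frame(gene = paste0("a", 1:4), species = rep("a", 4))
  rsym <- root_search(tsym, ssym, msym, cost_scheme(3, 2, 100), "DTL")
  expect_equal(sum(rsym$table$best), nrow(rsym$table))
  expect_equal(min(rsym$table$score), 9)
})

test_that("batch bookkeeping identity holds in every cell", {
  set.seed(71)
  ts <- random_species_tree(5, 3, seed = 12)
  trees <- list(); maps <- list()
  for (i in 1:10) {
    ph <- simulate_history(sim_config(ts, r_dup = 0.2, r_trans = 0.2,
                                      r_loss = 0.1), seed = 1100 + i)
    if (ph$extinct || sum(ph$gene_tree$is_leaf) < 2 ||
        sum(ph$gene_tree$is_leaf) > 12) next
    trees[[length(trees) + 1]] <- ph$gene_tree
    maps[[length(maps) + 1]] <- ph$map
  }
  br <- batch_reconcile(trees, ts, maps, models = c("DTI", "DTLI"),
                        tau = c(2.5, 6), max_histories = 300)
  expect_equal(nrow(br$cells), 4)
  for (r in seq_len(nrow(br$cells)))
    expect_equal(br$cells$retained[r] + br$cells$infeasible[r] +
                   br$cells$degenerate[r], length(trees))
  expect_s3_class(tidy(br), "tbl_df")
})

test_that("congruent collections aggregate to all-zero cells", {
  ts <- parse_newick("((a,b),(c,d));", "species")
  trees <- list(parse_newick("((a,b),(c,d));", "gene"),
                parse_newick("((a,b),(c,d));", "gene"))
  br <- batch_reconcile(trees, ts, NULL, models = c("DT", "DTL"),
                        tau = 2.5)
  expect_true(all(br$cells$n_dup == 0 & br$cells$n_trans == 0 &
                    br$cells$n_loss == 0))
  expect_true(all(br$cells$retained == 2))
  expect_true(all(br$cells$infeasible == 0 & br$cells$degenerate == 0))
})

test_that("degenerate-count trees are excluded from their cell", {
  fx <- fig_instance()
  # tau = 9 ties the duplication and transfer histories with conflicting
  # counts -> degenerate exclusion; tau = 10 retains the unique optimum
  br <- batch_reconcile(list(fx$tg), fx$ts,
                        attr(fx$map, "table"),
                        models = "DTLI", tau = c(9, 10))
  c9 <- br$cells[br$cells$tau == 9, ]
  c10 <- br$cells[br$cells$tau == 10, ]
  expect_equal(c9$degenerate, 1)
  expect_equal(c9$retained, 0)
  expect_equal(c10$retained, 1)
  expect_equal(c10$n_dup, 1)
  expect_equal(c10$n_loss, 3)
})

test_that("transfer matrices fold direction and key internal lineages", {
  ts <- parse_newick("((a,b),(c,d));", "species")
  # two paralog-free transfer instances with opposite directions
  tg1 <- parse_newick("((a1,c1),(a2,c2));", "gene")
  mp1 <- data.frame(gene = c("a1", "c1", "a2", "c2"),
                    species = c("a", "c", "a", "c"))
  br <- batch_reconcile(list(tg1), ts, mp1, models = "DTLI", tau = 1)
  tm <- transfer_matrix(br, "DTLI", 1)
  expect_true(isSymmetric(unclass(tm)))
  expect_true(all(diag(unclass(tm)) == 0))
  expect_equal(sum(unclass(tm)) / 2, sum(br$cells$n_trans))
})

test_that("highway detection applies the outlier rule", {
  nm <- paste0("s", 1:4)
  m <- matrix(0L, 4, 4, dimnames = list(nm, nm))
  # six unordered pairs with counts 10,1,1,1,1,1
  m["s1", "s2"] <- m["s2", "s1"] <- 10L
  m["s1", "s3"] <- m["s3", "s1"] <- 1L
  m["s1", "s4"] <- m["s4", "s1"] <- 1L
  m["s2", "s3"] <- m["s3", "s2"] <- 1L
  m["s2", "s4"] <- m["s4", "s2"] <- 1L
  m["s3", "s4"] <- m["s4", "s3"] <- 1L
  class(m) <- c("dtli_transfer_matrix", "matrix", "array")
  hw <- detect_highways(m)
  expect_equal(nrow(hw), 1)
  expect_setequal(c(hw$sp1, hw$sp2), c("s1", "s2"))
  expect_equal(attr(hw, "threshold"), 2.5 + 1.5 * sqrt(67.5 / 6))
  # uniform counts: nothing exceeds the mean
  u <- m; u[upper.tri(u) | lower.tri(u)] <- 3L
  expect_equal(nrow(detect_highways(u)), 0)
  # boundary: a count exactly at the threshold (uniform counts, zero SD)
  # is not flagged -- the rule is strictly "exceeding"
  m2 <- matrix(0L, 3, 3, dimnames = list(nm[1:3], nm[1:3]))
  m2["s1", "s2"] <- m2["s2", "s1"] <- 2L
  m2["s1", "s3"] <- m2["s3", "s1"] <- 2L
  m2["s2", "s3"] <- m2["s3", "s2"] <- 2L
  class(m2) <- c("dtli_transfer_matrix", "matrix", "array")
  expect_equal(nrow(detect_highways(m2)), 0)  # threshold = mean = count
  # scale equivariance
  m10 <- unclass(m) * 10L
  class(m10) <- c("dtli_transfer_matrix", "matrix", "array")
  expect_equal(detect_highways(m10)$n, detect_highways(m)$n * 10L)
  # guard
  one <- matrix(0L, 1, 1, dimnames = list("s1", "s1"))
  expect_error(detect_highways(one), "pairs")
})

test_that("autoplot methods return ggplot objects", {
  ts <- parse_newick("((a,b),(c,d));", "species")
  trees <- list(parse_newick("((a,b),(c,d));", "gene"))
  br <- batch_reconcile(trees, ts, NULL, models = "DTLI", tau = 2.5)
  expect_s3_class(autoplot(br), "ggplot")
  expect_s3_class(autoplot(transfer_matrix(br, "DTLI", 2.5)), "ggplot")
})
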