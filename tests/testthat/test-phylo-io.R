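test_that("Newick parsing enforces role invariants and preserves labels", {
  ts <- parse_newick("(a,(b,c,d));", "species")
  expect_equal(sum(ts$is_leaf), 4)
  expect_equal(sort(lengths(ts$children)[!ts$is_leaf]), c(2, 3))

  tg <- parse_newick("((a,b),(c,d));", "gene")
  expect_equal(sum(tg$is_leaf), 4)
  expect_equal(sum(!tg$is_leaf), 3)
  expect_true(all(lengths(tg$children)[!tg$is_leaf] == 2))

  expect_error(parse_newick("((a,b,c),d);", "gene"), "binary")
  expect_error(parse_newick("((a,b,c),d;", "species"), "position")
  expect_error(parse_newick("((a,a),b);", "gene"), "unique")

  # internal labels and branch lengths are accepted, lengths ignored
  t2 <- parse_newick("((a:1,b:2)ab:0.5,c:3)r;", "species")
  expect_true("ab" %in% t2$label)
})

test_that("parse -> write -> parse round-trips the topology", {
  set.seed(5)
  for (i in 1:10) {
    ts <- random_species_tree(sample(4:8, 1),
                              polytomy_size = if (i %% 2) 3 else NULL)
    t2 <- parse_newick(write_newick(ts), "species")
    expect_identical(write_newick(t2), write_newick(ts))
    expect_setequal(t2$label[t2$is_leaf], ts$label[ts$is_leaf])
  }
})

test_that("species index lca/ancestry agree with naive root-path logic", {
  ts <- parse_newick("(a,(b,c,d));", "species")
  idx <- build_species_index(ts)
  nm <- idx$names
  b <- which(nm == "b"); c_ <- which(nm == "c"); a <- which(nm == "a")
  poly <- which(nm == "b+c+d"); root <- which(nm == "a+b+c+d")
  expect_equal(idx$lca[b, c_], poly)
  expect_equal(idx$lca[a, c_], root)
  expect_true(is_incomparable(idx, a, b))
  expect_true(is_ancestor(idx, poly, b))
  expect_false(is_ancestor(idx, b, poly))

  # caterpillar summary quantities
  cat5 <- build_species_index(parse_newick("((((a,b),c),d),e);", "species"))
  expect_equal(cat5$h, 4)
  expect_equal(cat5$kstar, 2)
  expect_equal(cat5$n_poly, 0)

  # randomized: lca equals intersection of root paths
  set.seed(6)
  for (i in 1:5) {
    ts <- random_species_tree(sample(4:8, 1))
    idx <- build_species_index(ts)
    for (j in 1:20) {
      u <- sample(idx$n, 1); v <- sample(idx$n, 1)
      path <- function(x) { p <- x
        while (!is.na(ts$parent[p[length(p)]]))
          p <- c(p, ts$parent[p[length(p)]]); p }
      naive <- intersect(path(u), path(v))[1]
      expect_equal(idx$lca[u, v], naive)
    }
  }
})

test_that("child subsets enumerate the nonempty power set", {
  ts <- parse_newick("(a,(b,c,d));", "species")
  idx <- build_species_index(ts)
  poly <- which(idx$names == "b+c+d")
  expect_length(child_subsets(idx, poly), 2^3 - 1)
  leafa <- which(idx$names == "a")
  expect_identical(child_subsets(idx, leafa), 1L)
  expect_error(build_species_index(
    random_species_tree(14, polytomy_size = 13, seed = 1)), "force")
})

test_that("leaf mappings are validated and allow paralogs", {
  tg <- parse_newick("((g1,g2),g3);", "gene")
  ts <- parse_newick("(a,(b,c));", "species")
  mp <- read_leaf_mapping(
    data.frame(gene = c("g1", "g2", "g3"), species = c("a", "a", "b")),
    tg, ts)
  expect_s3_class(mp, "leaf_mapping")
  expect_equal(sum(!is.na(mp)), 3)
  expect_error(read_leaf_mapping(
    data.frame(gene = c("g1", "g2"), species = c("a", "b")), tg, ts),
    "missing")
  expect_error(read_leaf_mapping(
    data.frame(gene = c("g1", "g2", "g3"), species = c("a", "b", "z")),
    tg, ts), "absent")
  # suffix convention
  tg2 <- parse_newick("((x_a,y_b),z_c);", "gene")
  mp2 <- leaf_map_from_names(tg2, ts)
  expect_equal(attr(mp2, "table")$species, c("a", "b", "c"))
})

test_that("collapse_edge grows polytomies and preserves the leaf set", {
  ts <- parse_newick("((b,c),d);", "species")
  expect_equal(write_newick(collapse_edge(ts, "b+c")), "(b,c,d);")

  t1 <- parse_newick("(a,(b,(c,d)));", "species")
  t2 <- collapse_edge(t1, "c+d")
  expect_equal(write_newick(t2), "(a,(b,c,d));")
  expect_equal(build_species_index(t2)$kstar, 3)
  t3 <- collapse_edge(t2, "b+c+d")
  expect_equal(write_newick(t3), "(a,b,c,d);")
  expect_equal(build_species_index(t3)$kstar, 4)
  expect_equal(t3$n, t2$n - 1L)
  expect_setequal(t3$label[t3$is_leaf], t1$label[t1$is_leaf])

  expect_error(collapse_edge(t1, "a"), "leaf")
})
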