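# Shared fixtures: all built in code, no files.

# The four-taxon worked instance: binary gene tree vs a species tree whose
# (B,C,D) clade is collapsed to a polytomy.
fig_instance <- function() {
  tg <- parse_newick("((A,B),(C,D));", "gene")
  ts <- parse_newick("(A,(B,C,D));", "species")
  map <- data.frame(gene = c("A", "B", "C", "D"),
                    species = c("A", "B", "C", "D"))
  list(tg = tg, ts = ts, index = build_species_index(ts),
       map = read_leaf_mapping(map, tg, ts))
}

# Random binary gene tree over the given leaf labels.
random_gene_tree <- function(labels) {
  items <- as.list(labels)
  while (length(items) > 1L) {
    j <- sample(length(items), 2L)
    items <- c(items[-j],
               list(paste0("(", items[[j[1]]], ",", items[[j[2]]], ")")))
  }
  parse_newick(paste0(items[[1]], ";"), "gene")
}

# Random small reconciliation instance within the oracle guard.
random_instance <- function(allow_polytomy = TRUE) {
  nsp <- sample(3:5, 1)
  poly <- if (allow_polytomy && nsp >= 4 && runif(1) < 0.6)
    sample(3:min(4, nsp), 1) else NULL
  ts <- random_species_tree(nsp, poly)
  ngl <- sample(3:5, 1)
  gl <- paste0("g", seq_len(ngl))
  gsp <- sample(leaf_labels(ts), ngl, replace = TRUE)
  tg <- random_gene_tree(gl)
  list(tg = tg, ts = ts, index = build_species_index(ts),
       map = read_leaf_mapping(data.frame(gene = gl, species = gsp),
                               tg, ts),
       has_polytomy = !is.null(poly))
}

random_costs <- function() {
  # half-integer weights keep floating-point ties exact
  cost_scheme(dup = sample(c(1, 2, 3), 1),
              loss = sample(c(0, 0.5, 1, 2), 1),
              trans = sample(c(1, 2.5, 4, 10), 1))
}

history_signatures <- function(sols) {
  sort(vapply(sols$histories, function(h) paste(h$M, collapse = ","), ""))
}

# A hand-built two-transfer history whose timing graph contains a directed
# cycle: an ancestral transfer a -> d followed, deeper in the gene tree, by
# a transfer d -> (a,b,c)-ancestor.  The ordering constraint puts the (a,b)
# ancestor before the (a,b,c) ancestor, while species ancestry says the
# opposite.
cyclic_history <- function() {
  ts <- parse_newick("(((a,b),c),(d,e));", "species")
  index <- build_species_index(ts)
  tg <- parse_newick("(a1,(d1,(b1,c1)));", "gene")
  # post-order ids: a1,d1,b1,c1,(b1,c1),(d1,(b1,c1)),root
  # species post-order: a,b,(a,b),c,(a,b,c),d,e,(d,e),root
  structure(list(
    M = c(1L, 6L, 2L, 4L, 5L, 6L, 1L),
    horizontal = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    tg = tg, index = index), class = "dtli_history")
}
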