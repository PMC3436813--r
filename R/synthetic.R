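# Synthetic data: random species trees, gene trees with planted
# duplication/transfer/loss/ILS histories, and brute-force oracles used to
# validate the dynamic program and the feasibility test on small
# instances.

#' Random rooted species tree, optionally with a polytomy
#'
#' Draws a uniform random binary topology and, if requested, collapses
#' internal edges until one node reaches the requested out-degree, mimicking
#' the practice of collapsing short, poorly supported edges to mark
#' lineages where lineage sorting should be entertained.
#'
#' @param n Number of species leaves (>= 2); leaves are named `s1..sn`.
#' @param polytomy_size Target out-degree of the largest node (NULL keeps
#'   the tree binary; must be <= n).
#' @param seed Optional integer seed.
#' @return A species `recon_tree`.
#' @export
random_species_tree <- function(n, polytomy_size = NULL, seed = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(polytomy_size) && polytomy_size > n)
    stop("polytomy_size cannot exceed the number of leaves", call. = FALSE)
  phy <- ape::rtopology(n, rooted = TRUE)
  phy$tip.label <- paste0("s", seq_len(n))
  ts <- tree_from_phylo(phy, "species")
  if (!is.null(polytomy_size)) {
    while (max(lengths(ts$children)) < polytomy_size) {
      deg <- lengths(ts$children)
      v <- which.max(deg)
      internal_kids <- ts$children[[v]][!ts$is_leaf[ts$children[[v]]]]
      if (length(internal_kids)) {
        # prefer collapsing a binary child: grows the polytomy by 1
        kdeg <- lengths(ts$children)[internal_kids]
        pick <- internal_kids[order(kdeg)][1]
        ts <- collapse_edge(ts, pick)
      } else if (!is.na(ts$parent[v])) {
        ts <- collapse_edge(ts, v)
      } else {
        stop("cannot grow polytomy to requested size", call. = FALSE)
      }
    }
  }
  ts
}

#' Simulation settings for planted gene-family histories
#'
#' @param species_tree A species `recon_tree`.
#' @param r_dup,r_trans,r_loss Expected numbers of duplications, transfers
#'   and losses per gene lineage per species-tree edge (Poisson-distributed
#'   counts).
#' @param ils One of `"hard"` (each gene lineage crossing a polytomy sorts
#'   through its own independently drawn binary resolution) or `"soft"`
#'   (all lineages in one simulation share a single resolution per
#'   polytomy).
#' @return A `sim_config` list.
#' @export
sim_config <- function(species_tree, r_dup = 0, r_trans = 0, r_loss = 0,
                       ils = c("hard", "soft")) {
  stopifnot(inherits(species_tree, "recon_tree"),
            species_tree$role == "species",
            r_dup >= 0, r_trans >= 0, r_loss >= 0)
  structure(list(species_tree = species_tree, r_dup = r_dup,
                 r_trans = r_trans, r_loss = r_loss,
                 ils = match.arg(ils)),
            class = "sim_config")
}

#' Simulate a gene tree with a planted event history
#'
#' A single gene lineage enters the species tree at the root and evolves
#' towards the leaves.  On each species-tree edge the lineage draws
#' Poisson numbers of duplications (copy in place), transfers (copy moves
#' to a uniformly chosen incomparable species lineage) and losses
#' (termination), applied in random order.  At a binary species node the
#' lineage co-diverges into both children; at a polytomy it sorts through
#' a random binary resolution.  Subtrees whose copies all die are pruned
#' from the observed gene tree, but their planted events remain on record,
#' so the planted cost is an upper bound on the optimal reconciliation
#' score.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; the seed fixes the full output.
#' @return A `planted_history` list: `gene_tree`, `map` (leaf-mapping
#'   tibble), `events` (type, species, donor, recipient), `n_dup`,
#'   `n_trans`, `n_loss`, and `extinct` (TRUE when no gene leaf survived;
#'   the caller should retry with another seed).
#' @export
simulate_history <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ts <- config$species_tree
  index <- build_species_index(ts, force = TRUE)
  counter <- new.env(parent = emptyenv())
  events <- list()
  log_event <- function(type, species, donor = NA, recipient = NA) {
    events[[length(events) + 1L]] <<- tibble::tibble(
      type = type, species = index$names[species],
      donor = if (is.na(donor)) NA_character_ else index$names[donor],
      recipient = if (is.na(recipient)) NA_character_
                  else index$names[recipient])
  }
  soft_res <- new.env(parent = emptyenv())   # shared resolutions (soft ILS)
  incomp <- lapply(seq_len(ts$n), function(s)
    which(!index$anc[s, ] & !index$anc[, s]))

  join <- function(a, b) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(kind = "node", left = a, right = b)
  }
  # one lineage entering the edge above species s
  evolve <- function(s, depth = 0L) {
    if (depth > 50L) return(NULL)  # guard against runaway growth
    ev <- c(rep("D", rpois(1, config$r_dup)),
            rep("T", rpois(1, config$r_trans)),
            rep("L", rpois(1, config$r_loss)))
    ev <- sample(ev)
    for (e in ev) {
      if (e == "L") { log_event("loss", s); return(NULL) }
      if (e == "D") {
        log_event("duplication", s)
        copy <- evolve(s, depth + 1L)
        rest <- descend_after(s, depth)
        return(join(rest, copy))
      }
      if (e == "T") {
        if (!length(incomp[[s]])) next   # no incomparable lineage exists
        rec <- incomp[[s]][sample.int(length(incomp[[s]]), 1L)]
        log_event("transfer", s, donor = s, recipient = rec)
        copy <- evolve(rec, depth + 1L)
        rest <- descend_after(s, depth)
        return(join(rest, copy))
      }
    }
    descend(s, depth)
  }
  # remaining evolution of the resident lineage after an in-edge event:
  # it continues on the same edge (fresh event draws) rather than jumping
  # straight to the divergence, keeping event order unconstrained
  descend_after <- function(s, depth) evolve(s, depth + 1L)
  descend <- function(s, depth) {
    if (ts$is_leaf[s]) {
      k <- (counter[[as.character(s)]] %||% 0L) + 1L
      counter[[as.character(s)]] <- k
      return(list(kind = "leaf",
                  label = paste0(ts$label[s], "_", k),
                  species = ts$label[s]))
    }
    kids <- ts$children[[s]]
    if (length(kids) == 2L) {
      return(join(evolve(kids[1], depth + 1L), evolve(kids[2], depth + 1L)))
    }
    # polytomy: sort through a binary resolution
    res <- if (config$ils == "soft") {
      key <- as.character(s)
      if (is.null(soft_res[[key]]))
        soft_res[[key]] <- random_resolution(kids)
      soft_res[[key]]
    } else random_resolution(kids)
    build_res <- function(r) {
      if (!is.list(r)) return(evolve(r, depth + 1L))
      join(build_res(r$left), build_res(r$right))
    }
    build_res(res)
  }
  # uniform random rooted binary resolution over a set of species nodes
  random_resolution <- function(nodes) {
    items <- as.list(nodes)
    while (length(items) > 1L) {
      i <- sample.int(length(items), 2L)
      merged <- list(left = items[[i[1]]], right = items[[i[2]]])
      items <- c(items[-i], list(merged))
    }
    items[[1]]
  }

  gt <- evolve(ts$root)
  events <- if (length(events)) dplyr::bind_rows(events)
            else tibble::tibble(type = character(0), species = character(0),
                                donor = character(0),
                                recipient = character(0))
  if (is.null(gt) || gt$kind == "leaf") {
    # all lineages died, or a single copy survived: nothing to reconcile
    return(structure(list(gene_tree = NULL, map = NULL, events = events,
                          extinct = TRUE), class = "planted_history"))
  }
  nwk <- paste0(tree_text(gt), ";")
  gene_tree <- parse_newick(nwk, "gene")
  leaves <- collect_leaves(gt)
  map <- tibble::tibble(gene = vapply(leaves, `[[`, "", "label"),
                        species = vapply(leaves, `[[`, "", "species"))
  structure(list(
    gene_tree = gene_tree, map = map, events = events,
    n_dup = sum(events$type == "duplication"),
    n_trans = sum(events$type == "transfer"),
    n_loss = sum(events$type == "loss"),
    extinct = FALSE), class = "planted_history")
}

tree_text <- function(x) {
  if (x$kind == "leaf") return(x$label)
  paste0("(", tree_text(x$left), ",", tree_text(x$right), ")")
}

collect_leaves <- function(x) {
  if (x$kind == "leaf") return(list(x))
  c(collect_leaves(x$left), collect_leaves(x$right))
}

#' @export
print.planted_history <- function(x, ...) {
  if (x$extinct) cat("<planted_history  extinct>\n")
  else cat(sprintf("<planted_history  %d leaves: %dD %dT %dL planted>\n",
                   sum(x$gene_tree$is_leaf), x$n_dup, x$n_trans, x$n_loss))
  invisible(x)
}

# Brute-force oracles --------------------------------------------------------

#' Exhaustive reconciliation by assignment enumeration
#'
#' Independent oracle for [first_pass()]/[second_pass()] on small
#' instances.  Because the leaf mapping plus a species assignment for
#' every internal gene node determines the vertical-inheritance sets,
#' events, transfer edges and losses of a history, the oracle simply
#' enumerates all `|V_S|^k` assignment vectors (k internal nodes), scores
#' each with its own recursive, set-based scorer (no bitmasks, no tables)
#' and returns the argmin set.
#'
#' @param tg,ts,map,costs,model As in [first_pass()].
#' @return List: `score`, `n_histories`, `assignments` (matrix, one row
#'   per optimal history, columns = gene nodes, entries = species node
#'   ids), and `signatures` (canonical per-history strings).
#' @export
brute_force_reconcile <- function(tg, ts, map, costs, model = "DTLI") {
  index <- if (inherits(ts, "species_index")) ts else build_species_index(ts)
  ts <- index$tree
  if (sum(tg$is_leaf) > 6 || index$n > 11)
    stop("oracle guard: instance too large (<= 6 gene leaves, ",
         "<= 11 species nodes)", call. = FALSE)
  mi <- model_info(model)
  if (!mi$allows_polytomy && index$n_poly > 0L)
    stop("model ", mi$model, " requires a binary species tree", call. = FALSE)
  lam <- if (mi$losses_in_score) costs$lambda else 0
  internal <- which(!tg$is_leaf)
  po <- postorder_ids(tg$children, tg$root)
  grid <- as.matrix(do.call(expand.grid,
                            rep(list(seq_len(index$n)), length(internal))))
  score_one <- function(assign) {
    M <- map
    M[internal] <- assign
    sigma <- vector("list", tg$n)   # species-node-id sets
    evs <- rep(NA_character_, tg$n)
    total <- 0
    for (g in po) {
      if (tg$is_leaf[g]) { sigma[[g]] <- M[g]; next }
      ch <- tg$children[[g]]
      A <- vector("list", 2L); hor <- logical(2L)
      for (i in 1:2) {
        sc <- M[ch[i]]; s <- M[g]
        if (sc == s) { A[[i]] <- sigma[[ch[i]]] }
        else if (index$anc[s, sc]) {
          v <- sc
          while (ts$parent[v] != s) v <- ts$parent[v]
          A[[i]] <- v
        } else if (index$anc[sc, s]) return(Inf)
        else { hor[i] <- TRUE; A[[i]] <- integer(0) }
      }
      if (all(hor)) return(Inf)
      ev <- if (length(intersect(A[[1]], A[[2]]))) "dup"
            else if (any(hor)) "trans"
            else if (index$is_poly[M[g]]) "coal" else "spec"
      evs[g] <- ev
      total <- total + switch(ev, dup = costs$delta, trans = costs$tau, 0)
      for (i in 1:2)
        total <- total + lam *
          oracle_edge_losses(index, ev, M[g], M[ch[i]], sigma[[ch[i]]],
                             hor[i],
                             child_codiv = evs[ch[i]] %in%
                               c("spec", "coal"))
      sigma[[g]] <- sort(unique(c(A[[1]], A[[2]])))
    }
    total
  }
  scores <- apply(grid, 1L, score_one)
  opt <- min(scores)
  sel <- which(scores <= opt + COST_EPS)
  assignments <- matrix(map, nrow = length(sel), ncol = tg$n, byrow = TRUE)
  assignments[, internal] <- grid[sel, , drop = FALSE]
  list(score = opt, n_histories = length(sel), assignments = assignments,
       signatures = sort(apply(assignments, 1L, paste, collapse = ",")))
}

# Set-based loss count for the oracle: walks parent pointers, no
# precomputed path tables.
oracle_edge_losses <- function(index, event, s, sc, sigma_c, horizontal,
                               child_codiv = TRUE) {
  ts <- index$tree
  node_loss <- function(v, covered) {
    if (ts$is_leaf[v]) return(0L)
    unc <- setdiff(ts$children[[v]], covered)
    if (!length(unc)) return(0L)
    if (length(ts$children[[v]]) > 2L) 1L else length(unc)
  }
  term_cov <- if (ts$is_leaf[sc]) sc else sigma_c
  # incomplete coverage at the child itself is charged only when the
  # child co-diverges there; a duplication/transfer child's copies are
  # charged on their own outgoing edges
  term_loss <- if (child_codiv) node_loss(sc, term_cov) else 0L
  if (horizontal) return(term_loss)
  # path s .. sc by walking up from sc
  path <- sc; v <- sc
  while (v != s) { v <- ts$parent[v]; path <- c(v, path) }
  if (event %in% c("spec", "coal")) path <- path[-1L]
  n <- 0L
  for (i in seq_along(path)) {
    v <- path[i]
    if (v == sc) n <- n + term_loss
    else n <- n + node_loss(v, path[i + 1L])
  }
  n
}

#' Brute-force temporal feasibility by total-order search
#'
#' Checks whether some permutation of the timing-graph vertices satisfies
#' every "predates" constraint; agrees with the acyclicity test but makes
#' no use of topological sorting.  Guarded to small graphs.
#'
#' @param graph A `timing_graph`.
#' @return TRUE iff a consistent total order of the vertices exists.
#' @export
feasible_by_order_search <- function(graph) {
  stopifnot(inherits(graph, "timing_graph"))
  v <- graph$vertices
  if (length(v) > 8)
    stop("order-search guard: more than 8 vertices", call. = FALSE)
  if (nrow(graph$edges) == 0L) return(TRUE)
  ranks <- perm_ranks(length(v))
  from <- match(graph$edges$from, v)
  to <- match(graph$edges$to, v)
  ok <- rep(TRUE, nrow(ranks))
  for (e in seq_along(from))
    ok <- ok & (ranks[, from[e]] < ranks[, to[e]])
  any(ok)
}

# ranks[i, v] = position of vertex v in the i-th total order
perm_ranks <- function(n) {
  key <- paste0("r", n)
  hit <- perm_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- all_permutations(n)
  r <- matrix(0L, nrow(p), n)
  for (j in seq_len(n)) r[cbind(seq_len(nrow(p)), p[, j])] <- j
  perm_cache[[key]] <- r
  r
}

perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  hit <- perm_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- if (n == 1L) matrix(1L, 1, 1) else {
    sub <- all_permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k)
      cbind(k, ifelse(sub >= k, sub + 1L, sub))))
  }
  perm_cache[[key]] <- out
  out
}
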