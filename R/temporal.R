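# Temporal feasibility of transfer histories.
#
# Every horizontal transfer requires its donor and recipient lineages to
# have coexisted.  A history is feasible iff some ordering of species
# divergences satisfies all transfer-implied constraints, which holds iff
# the directed timing graph built below is acyclic.

#' Build the timing graph of a reconciliation history
#'
#' Vertices are the species that act as donor or recipient of some
#' transfer (plus their parents, which class-2 constraints reference).
#' Directed edges, read "predates", come in three classes:
#' \describe{
#'   \item{ancestry}{a strict ancestor in the species tree predates its
#'     descendants;}
#'   \item{ordering}{if one transfer lies at-or-above another on the same
#'     gene-tree lineage, the parents of the earlier transfer's donor and
#'     recipient predate the later transfer's donor and recipient (applied
#'     reflexively, which encodes that each transfer happened while both
#'     of its own lineages existed);}
#'   \item{contemporaneity}{donor and recipient must be contemporaneous,
#'     so anything that predates one side of a transfer also predates the
#'     other; propagated to fixpoint.}
#' }
#'
#' @param history A `dtli_history`.
#' @param index Optional `species_index` (taken from the history if
#'   omitted).
#' @return A `timing_graph`: list with `vertices` (species node ids),
#'   `core` (the donor/recipient set itself), `edges` (tibble `from`,
#'   `to`, `class`) and `names`.
#' @export
build_timing_graph <- function(history, index = NULL) {
  h <- history
  if (is.null(index)) index <- h$index
  tg <- h$tg
  tr_child <- which(h$horizontal)
  donors <- h$M[tg$parent[tr_child]]
  recips <- h$M[tr_child]
  core <- sort(unique(c(donors, recips)))
  if (!length(core)) {
    return(structure(list(
      vertices = integer(0), core = integer(0),
      edges = tibble::tibble(from = integer(0), to = integer(0),
                             class = character(0)),
      names = character(0), index = index), class = "timing_graph"))
  }
  parent_or_self <- function(v) {
    p <- index$tree$parent[v]
    ifelse(is.na(p), v, p)   # root donor/recipient: degrade to the root
  }
  ef <- integer(0); et <- integer(0); ecl <- character(0)
  add <- function(from, to, class) {
    keep <- from != to
    ef <<- c(ef, from[keep]); et <<- c(et, to[keep])
    ecl <<- c(ecl, rep(class, sum(keep)))
  }
  # class 2: ordering of transfers along comparable gene lineages
  ganc <- gene_ancestry(tg)
  tnode <- tg$parent[tr_child]   # donor-side gene node of each transfer
  for (i in seq_along(tr_child)) for (j in seq_along(tr_child)) {
    if (!ganc[tnode[i], tnode[j]]) next   # need g_i >=_G g_j
    pd <- parent_or_self(donors[i]); pr <- parent_or_self(recips[i])
    add(c(pd, pd, pr, pr), c(donors[j], recips[j], donors[j], recips[j]),
        "ordering")
  }
  verts <- sort(unique(c(core, ef, et)))
  # class 1: strict ancestry among all graph vertices
  for (u in verts) for (v in verts) {
    if (u != v && index$anc[u, v]) add(u, v, "ancestry")
  }
  # class 3: contemporaneity propagation, iterated to fixpoint
  partner_from <- c(donors, recips)
  partner_to <- c(recips, donors)
  repeat {
    added <- FALSE
    ekey <- paste(ef, et)
    for (p in seq_along(partner_from)) {
      src <- unique(ef[et == partner_from[p]])
      for (s_i in src) {
        if (s_i == partner_to[p]) next
        if (!(paste(s_i, partner_to[p]) %in% ekey)) {
          add(s_i, partner_to[p], "contemporaneity")
          ekey <- c(ekey, paste(s_i, partner_to[p]))
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  verts <- sort(unique(c(verts, ef, et)))
  ed <- unique(tibble::tibble(from = ef, to = et, class = ecl))
  structure(list(vertices = verts, core = core, edges = ed,
                 names = index$names[verts], index = index),
            class = "timing_graph")
}

gene_ancestry <- function(tg) {
  anc <- matrix(FALSE, tg$n, tg$n)
  for (v in seq_len(tg$n)) {
    u <- v
    while (!is.na(u)) { anc[u, v] <- TRUE; u <- tg$parent[u] }
  }
  anc
}

#' @export
print.timing_graph <- function(x, ...) {
  cat(sprintf("<timing_graph  %d vertices, %d edges>\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Is a timing graph acyclic?
#'
#' A history is temporally feasible iff its timing graph has no directed
#' cycle (checked by topological sorting, linear in graph size).
#'
#' @param graph A `timing_graph` from [build_timing_graph()].
#' @return TRUE iff the graph is acyclic.
#' @export
is_temporally_feasible <- function(graph) {
  stopifnot(inherits(graph, "timing_graph"))
  if (nrow(graph$edges) == 0L) return(TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$edges$from),
               to = as.character(graph$edges$to)),
    directed = TRUE,
    vertices = data.frame(name = as.character(graph$vertices)))
  igraph::is_dag(g)
}

#' Filter a solution set for temporal feasibility
#'
#' Builds the timing graph of every enumerated history and flags each as
#' feasible or not.  Histories are retained (with their flag) so that the
#' pre-filter count stays observable; use the flags or [tidy()] to take
#' the feasible view.  When every optimal history is infeasible the
#' status is set to `"all_optimal_infeasible"` (finding an optimal
#' feasible history in that situation is a harder problem and is not
#' attempted).
#'
#' @param sols A `dtli_solutions` object.
#' @return The solution set with `feasible` flags and `status` filled.
#' @export
filter_feasible <- function(sols) {
  stopifnot(inherits(sols, "dtli_solutions"))
  feas <- vapply(sols$histories, function(h)
    is_temporally_feasible(build_timing_graph(h)), TRUE)
  sols$feasible <- feas
  sols$status <- if (length(feas) && !any(feas)) "all_optimal_infeasible"
                 else "ok"
  sols
}

#' Histories that passed the feasibility filter
#'
#' @param sols A `dtli_solutions` object (after [filter_feasible()]).
#' @return List of feasible `dtli_history` objects.
#' @export
feasible_histories <- function(sols) {
  stopifnot(inherits(sols, "dtli_solutions"))
  sols$histories[which(sols$feasible %in% TRUE)]
}
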