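#' Reconcile a gene tree with a species tree
#'
#' The main entry point: runs the dynamic program ([first_pass()]),
#' enumerates all optimal histories ([second_pass()]) and screens each
#' for temporal feasibility ([filter_feasible()]).
#'
#' @param tg Rooted binary gene tree: a `recon_tree` or a Newick string.
#' @param ts Rooted species tree (may contain polytomies): a `recon_tree`,
#'   a `species_index`, or a Newick string.
#' @param map A `leaf_mapping`, or anything [read_leaf_mapping()] accepts
#'   (two-column data frame or TSV path).
#' @param costs A [cost_scheme()].
#' @param model `"DT"`, `"DTI"`, `"DTL"` or `"DTLI"` (default).
#' @param max_histories Enumeration cap for the traceback.
#' @param check_feasibility Run the timing-graph screen (default TRUE).
#' @return A `dtli_solutions` object.
#' @examples
#' sols <- reconcile("((A,B),(C,D));", "(A,(B,C,D));",
#'                   data.frame(gene = c("A", "B", "C", "D"),
#'                              species = c("A", "B", "C", "D")),
#'                   cost_scheme(dup = 3, loss = 2, trans = 7))
#' sols
#' tidy(sols)
#' @export
reconcile <- function(tg, ts, map, costs, model = "DTLI",
                      max_histories = 10000, check_feasibility = TRUE) {
  if (is.character(tg)) tg <- parse_newick(tg, "gene")
  if (is.character(ts)) ts <- parse_newick(ts, "species")
  index <- if (inherits(ts, "species_index")) ts else build_species_index(ts)
  if (!inherits(map, "leaf_mapping"))
    map <- read_leaf_mapping(map, tg, index$tree)
  dp <- first_pass(tg, index, map, costs, model)
  sols <- second_pass(dp, max_histories = max_histories)
  if (check_feasibility) sols <- filter_feasible(sols)
  sols
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-history event counts of a solution set
#'
#' @param x A `dtli_solutions` object.
#' @param ... Unused.
#' @return A tibble with one row per optimal history: event counts, the
#'   rescored total and the temporal-feasibility flag.
#' @method tidy dtli_solutions
#' @export
tidy.dtli_solutions <- function(x, ...) {
  s <- summarize_events(x)
  dplyr::mutate(s$counts,
                score = vapply(x$histories, function(h) h$score, 0),
                .after = "history")
}

#' One-row summary of a reconciliation
#'
#' @param x A `dtli_solutions` object.
#' @param ... Unused.
#' @method glance dtli_solutions
#' @export
glance.dtli_solutions <- function(x, ...) {
  s <- summarize_events(x)
  tibble::tibble(
    model = x$model, score = x$score, n_optimal = x$n_optimal,
    n_enumerated = length(x$histories),
    n_feasible = sum(x$feasible %in% TRUE),
    degenerate = s$degenerate, truncated = x$truncated,
    status = x$status,
    delta = x$costs$delta, lambda = x$costs$lambda, tau = x$costs$tau)
}

#' Node-level annotations of one history
#'
#' @param x A `dtli_history` object.
#' @param ... Unused.
#' @return The per-node annotation tibble (species assignment and event).
#' @method tidy dtli_history
#' @export
tidy.dtli_history <- function(x, ...) x$nodes
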