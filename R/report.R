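# Batch reconciliation, event-parsimony rooting, transfer matrices and
# highway detection.

#' Root a gene tree by event parsimony
#'
#' Reconciles the gene tree rooted on every edge of its unrooted version
#' and reports all rootings achieving the minimum score.
#'
#' @param tg Gene tree (rooted arbitrarily; the search covers all edges).
#' @param ts Species tree, `species_index` or Newick string.
#' @param map Leaf mapping (any form accepted by [reconcile()]); applies
#'   to every rooting (leaf labels are unchanged by rerooting).
#' @param costs A [cost_scheme()].
#' @param model Model variant.
#' @return A `dtli_root_search`: tibble `table` (one row per distinct
#'   rooting: `newick`, `score`, `best`), and `best` — a list of
#'   `dtli_solutions` (with feasibility flags), one per optimal rooting.
#' @export
root_search <- function(tg, ts, map, costs, model = "DTLI") {
  if (is.character(tg)) tg <- parse_newick(tg, "gene")
  index <- if (inherits(ts, "species_index")) ts
           else build_species_index(if (is.character(ts))
             parse_newick(ts, "species") else ts)
  rootings <- all_rootings(tg)
  if (!inherits(map, "leaf_mapping"))
    map_tbl <- if (is.character(map) && length(map) == 1L)
      utils::read.table(map, sep = "\t", header = FALSE,
                        col.names = c("gene", "species"),
                        colClasses = "character")
    else as.data.frame(map)
  else map_tbl <- attr(map, "table")
  scores <- numeric(length(rootings))
  dps <- vector("list", length(rootings))
  for (i in seq_along(rootings)) {
    tgi <- rootings[[i]]
    mpi <- read_leaf_mapping(map_tbl, tgi, index$tree)
    dps[[i]] <- first_pass(tgi, index, mpi, costs, model)
    scores[i] <- dps[[i]]$score
  }
  best <- which(scores <= min(scores) + COST_EPS)
  sols <- lapply(best, function(i) filter_feasible(second_pass(dps[[i]])))
  structure(list(
    table = tibble::tibble(
      newick = vapply(rootings, write_newick, ""),
      score = scores, best = seq_along(rootings) %in% best),
    best = sols), class = "dtli_root_search")
}

#' @export
print.dtli_root_search <- function(x, ...) {
  cat(sprintf("<dtli_root_search  %d rootings, best score %.6g (%d root%s)>\n",
              nrow(x$table), min(x$table$score), length(x$best),
              if (length(x$best) == 1) "" else "s"))
  invisible(x)
}

# All distinct rooted binary trees obtainable by rooting the unrooted
# version of tg on one of its edges (2n-3 of them for n leaves).
all_rootings <- function(tg) {
  phy <- as_phylo(tg)
  tips <- leaf_labels(tg)
  if (length(tips) == 2L) return(list(tg))
  un <- ape::unroot(phy)
  seen <- character(0)
  out <- list()
  for (v in seq_len(tg$n)) {
    if (v == tg$root) next
    cl <- sort(tg$label[tg$is_leaf & descends_from(tg, v)])
    comp <- sort(setdiff(tips, cl))
    if (!length(comp)) next
    key <- paste(min(paste(cl, collapse = ","),
                     paste(comp, collapse = ",")),
                 max(paste(cl, collapse = ","),
                     paste(comp, collapse = ",")))
    if (key %in% seen) next
    seen <- c(seen, key)
    og <- if (length(cl) <= length(comp)) cl else comp
    rooted <- ape::root(un, outgroup = og, resolve.root = TRUE)
    out[[length(out) + 1L]] <-
      parse_newick(ape::write.tree(rooted), "gene")
  }
  out
}

#' Batch reconciliation over a gene-tree collection
#'
#' Reconciles every tree under every model/transfer-cost combination and
#' aggregates event counts with the standard retention protocol: in each
#' cell a tree is excluded as infeasible if no optimal history passes the
#' temporal screen, and excluded as degenerate if its optimal histories
#' disagree in any event count.  Under the default `exclusion =
#' "cross_model"` policy, a tree with no feasible solution for at least
#' one parameter setting is eliminated from every cell.
#'
#' @param trees List of gene trees (recon_tree or Newick strings),
#'   optionally named.
#' @param ts Species tree (or index, or Newick).
#' @param maps A single leaf-mapping table applying to all trees, or a
#'   list of per-tree tables; `NULL` maps gene leaves to the species of
#'   the same name.
#' @param models Character vector of model variants.
#' @param tau Numeric vector of transfer costs to sweep.
#' @param dup,loss Duplication and loss weights.
#' @param exclusion `"cross_model"` (default) or `"per_cell"` infeasibility
#'   policy.
#' @param max_histories Per-tree enumeration cap.
#' @return A `dtli_batch`: `cells` (one row per model/tau: summed event
#'   counts over retained trees plus exclusion tallies), `per_tree`
#'   (per-tree records) and `transfers` (per retained tree and cell,
#'   donor/recipient tallies feeding [transfer_matrix()]).
#' @export
batch_reconcile <- function(trees, ts, maps = NULL,
                            models = c("DT", "DTI", "DTL", "DTLI"),
                            tau = c(2.5, 6, 10), dup = 3, loss = 2,
                            exclusion = c("cross_model", "per_cell"),
                            max_histories = 10000) {
  exclusion <- match.arg(exclusion)
  index <- if (inherits(ts, "species_index")) ts
           else build_species_index(if (is.character(ts))
             parse_newick(ts, "species") else ts)
  trees <- lapply(trees, function(t)
    if (is.character(t)) parse_newick(t, "gene") else t)
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    names(trees) <- paste0("tree", seq_along(trees))
  per <- list(); trrows <- list()
  for (ti in seq_along(trees)) {
    tgi <- trees[[ti]]
    mp <- if (is.null(maps)) {
      tibble::tibble(gene = leaf_labels(tgi), species = leaf_labels(tgi))
    } else if (is.data.frame(maps)) maps else maps[[ti]]
    mpi <- read_leaf_mapping(mp, tgi, index$tree)
    for (model in models) for (tv in tau) {
      res <- tryCatch({
        sols <- reconcile(tgi, index, mpi,
                          cost_scheme(dup = dup, loss = loss, trans = tv),
                          model = model, max_histories = max_histories)
        summ <- summarize_events(sols)
        feas_idx <- which(sols$feasible %in% TRUE)
        cnt <- if (length(feas_idx))
          summ$counts[summ$counts$history == feas_idx[1], ] else NULL
        row <- tibble::tibble(
          tree = names(trees)[ti], model = model, tau = tv,
          score = sols$score, n_optimal = sols$n_optimal,
          feasible_any = length(feas_idx) > 0,
          degenerate = summ$degenerate,
          n_dup = if (is.null(cnt)) NA_integer_ else cnt$n_dup,
          n_trans = if (is.null(cnt)) NA_integer_ else cnt$n_trans,
          n_loss = if (is.null(cnt)) NA_integer_ else cnt$n_loss,
          n_coal = if (is.null(cnt)) NA_integer_ else cnt$n_coal,
          error = NA_character_)
        trr <- if (length(feas_idx) && !summ$degenerate) {
          h <- sols$histories[[feas_idx[1]]]
          if (nrow(h$transfers)) tibble::tibble(
            tree = names(trees)[ti], model = model, tau = tv,
            h$transfers[, c("donor", "recipient")]) else NULL
        } else NULL
        list(row = row, trr = trr)
      }, error = function(e) list(row = tibble::tibble(
        tree = names(trees)[ti], model = model, tau = tv,
        score = NA_real_, n_optimal = NA_real_, feasible_any = NA,
        degenerate = NA, n_dup = NA_integer_, n_trans = NA_integer_,
        n_loss = NA_integer_, n_coal = NA_integer_,
        error = conditionMessage(e)), trr = NULL))
      per[[length(per) + 1L]] <- res$row
      if (!is.null(res$trr)) trrows[[length(trrows) + 1L]] <- res$trr
    }
  }
  per_tree <- dplyr::bind_rows(per)
  # retention flags
  bad_cross <- unique(per_tree$tree[per_tree$feasible_any %in% FALSE])
  per_tree <- dplyr::mutate(
    per_tree,
    excluded_infeasible = if (exclusion == "cross_model")
      .data$tree %in% bad_cross else .data$feasible_any %in% FALSE,
    excluded_degenerate = !.data$excluded_infeasible &
      .data$degenerate %in% TRUE,
    retained = is.na(.data$error) &
      !.data$excluded_infeasible & !.data$excluded_degenerate)
  transfers <- if (length(trrows)) dplyr::bind_rows(trrows)
    else tibble::tibble(tree = character(0), model = character(0),
                        tau = numeric(0), donor = character(0),
                        recipient = character(0))
  # drop transfer records of trees excluded under the cross-model policy
  transfers <- dplyr::semi_join(
    transfers, per_tree[per_tree$retained,
                        c("tree", "model", "tau")],
    by = c("tree", "model", "tau"))
  cells <- dplyr::summarise(
    dplyr::group_by(per_tree, .data$model, .data$tau),
    n_dup = sum(.data$n_dup[.data$retained]),
    n_trans = sum(.data$n_trans[.data$retained]),
    n_loss = sum(.data$n_loss[.data$retained]),
    n_coal = sum(.data$n_coal[.data$retained]),
    retained = sum(.data$retained),
    infeasible = sum(.data$excluded_infeasible),
    degenerate = sum(.data$excluded_degenerate),
    .groups = "drop")
  structure(list(cells = cells, per_tree = per_tree,
                 transfers = transfers, index = index,
                 n_trees = length(trees), exclusion = exclusion),
            class = "dtli_batch")
}

#' @export
print.dtli_batch <- function(x, ...) {
  cat(sprintf("<dtli_batch  %d trees, %d cells (%s exclusion)>\n",
              x$n_trees, nrow(x$cells), x$exclusion))
  print(x$cells)
  invisible(x)
}

#' @rdname batch_reconcile
#' @param x A `dtli_batch`.
#' @param ... Unused.
#' @method tidy dtli_batch
#' @export
tidy.dtli_batch <- function(x, ...) x$cells

#' Bidirectional transfer counts between species pairs
#'
#' Sums, over retained trees of one model/tau cell, the transfers between
#' each unordered species pair (both directions folded together).  Pairs
#' may involve ancestral (internal) species lineages; those are keyed by
#' internal node name.
#'
#' @param batch A `dtli_batch`.
#' @param model,tau The cell to tabulate.
#' @return A `dtli_transfer_matrix`: symmetric integer matrix over
#'   species-tree node names (attribute `pairs`: tidy pair tibble).
#' @export
transfer_matrix <- function(batch, model, tau) {
  stopifnot(inherits(batch, "dtli_batch"))
  tr <- batch$transfers
  tr <- tr[tr$model == model & tr$tau == tau, ]
  nm <- batch$index$names
  m <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  if (nrow(tr)) for (i in seq_len(nrow(tr))) {
    m[tr$donor[i], tr$recipient[i]] <- m[tr$donor[i], tr$recipient[i]] + 1L
    m[tr$recipient[i], tr$donor[i]] <- m[tr$recipient[i], tr$donor[i]] + 1L
  }
  structure(m, class = c("dtli_transfer_matrix", "matrix", "array"))
}

#' Detect transfer highways
#'
#' A highway is a species pair whose bidirectional transfer count is an
#' outlier: strictly exceeding the mean by `multiplier` population
#' standard deviations, both computed over all unordered pair counts
#' (zeros included).
#'
#' @param tm A `dtli_transfer_matrix` (or plain symmetric count matrix).
#' @param multiplier Outlier multiplier (default 1.5).
#' @return Tibble of flagged pairs: `sp1`, `sp2`, `n`, plus the threshold
#'   as attribute `"threshold"`.
#' @export
detect_highways <- function(tm, multiplier = 1.5) {
  m <- unclass(tm)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ut <- upper.tri(m)
  counts <- m[ut]
  if (length(counts) < 2L)
    stop("need at least 2 species pairs", call. = FALSE)
  mu <- mean(counts)
  sd_pop <- sqrt(mean((counts - mu)^2))
  thr <- mu + multiplier * sd_pop
  idx <- which(ut & m > thr, arr.ind = TRUE)
  out <- tibble::tibble(
    sp1 = rownames(m)[idx[, 1]], sp2 = colnames(m)[idx[, 2]],
    n = m[idx])
  out <- out[order(-out$n), ]
  attr(out, "threshold") <- thr
  out
}

#' Heatmap of a transfer matrix
#'
#' @param object A `dtli_transfer_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot dtli_transfer_matrix
#' @export
autoplot.dtli_transfer_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::pivot_longer(
    tibble::as_tibble(m, rownames = "donor"),
    -"donor", names_to = "recipient", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$donor, .data$recipient,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "transfers") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
ggplot2::autoplot

#' Event counts per model and transfer cost
#'
#' @param object A `dtli_batch`.
#' @param ... Unused.
#' @return A ggplot object (bars of summed event counts per cell).
#' @method autoplot dtli_batch
#' @export
autoplot.dtli_batch <- function(object, ...) {
  df <- tidyr::pivot_longer(object$cells,
                            c("n_dup", "n_trans", "n_loss", "n_coal"),
                            names_to = "event", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$tau), .data$n,
                                   fill = .data$event)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$model)) +
    ggplot2::labs(x = "transfer cost", y = "events over retained trees") +
    ggplot2::theme_minimal()
}
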