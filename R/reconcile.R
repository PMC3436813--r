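# Event codes used throughout the dynamic program (integer for speed).
EV_SPEC <- 1L; EV_COAL <- 2L; EV_DUP <- 3L; EV_TRANS <- 4L
EV_LABELS <- c("speciation", "coalescence", "duplication", "transfer")

# Cost comparisons use an absolute epsilon so that ties between
# floating-point cost sums are recognised deterministically.
COST_EPS <- 1e-9

#' Event cost scheme
#'
#' Duplication, loss and transfer carry user-chosen non-negative weights;
#' speciation and deep coalescence are free.  The defaults for duplication
#' and loss are the conventional 3 and 2; the transfer weight has no
#' natural default and must be supplied.
#'
#' @param dup Duplication weight (delta, >= 0).
#' @param loss Loss weight (lambda, >= 0).
#' @param trans Transfer weight (tau, >= 0); required.
#' @return A `cost_scheme` list with elements `delta`, `lambda`, `tau`.
#' @export
cost_scheme <- function(dup = 3, loss = 2, trans) {
  if (missing(trans))
    stop("the transfer cost `trans` has no default and must be supplied",
         call. = FALSE)
  stopifnot(is.finite(dup), is.finite(loss), is.finite(trans),
            dup >= 0, loss >= 0, trans >= 0)
  structure(list(delta = dup, lambda = loss, tau = trans),
            class = "cost_scheme")
}

# Model variants: the "L" letter switches losses into the optimisation
# criterion; the "I" letter permits species polytomies (deep coalescence).
model_info <- function(model) {
  model <- match.arg(model, c("DT", "DTI", "DTL", "DTLI"))
  list(model = model,
       losses_in_score = grepl("L", model, fixed = TRUE),
       allows_polytomy = grepl("I", model, fixed = TRUE))
}

event_kappa <- function(event, costs) {
  ifelse(event == EV_DUP, costs$delta,
         ifelse(event == EV_TRANS, costs$tau, 0))
}

#' Classify the event at a gene-tree node
#'
#' Given a candidate species assignment `s` for a gene node and the
#' assignments and vertical-inheritance sets of its two children, decides
#' which divergence event is implied.  The duplication test asks whether
#' the sets of children of `s` that inherit descendants of the two gene
#' children overlap; when they are disjoint the event is a transfer if one
#' child lies in a lineage incomparable to `s`, otherwise a co-divergence:
#' speciation at a binary node, deep coalescence at a polytomy.  At a
#' binary node the disjointness test coincides with classical lca
#' reconciliation.
#'
#' @param index A `species_index`.
#' @param s,s1,s2 Species assignments (node name or id) for the gene node
#'   and its two children.
#' @param sigma1,sigma2 Vertical-inheritance sets of the children: needed
#'   only when a child maps to `s` itself, as a character vector of child
#'   labels of that node (ignored otherwise).
#' @return One of `"speciation"`, `"coalescence"`, `"duplication"`,
#'   `"transfer"`, or `"invalid"` when no event is consistent (e.g. both
#'   children in lineages incomparable to `s`).
#' @export
classify_event <- function(index, s, s1, s2, sigma1 = NULL, sigma2 = NULL) {
  s  <- resolve_node(index, s)
  s1 <- resolve_node(index, s1); s2 <- resolve_node(index, s2)
  m1 <- resolve_sigma(index, s1, sigma1)
  m2 <- resolve_sigma(index, s2, sigma2)
  ev <- classify_event_code(index, s, s1, m1, s2, m2)
  if (is.na(ev)) "invalid" else EV_LABELS[ev]
}

resolve_node <- function(index, x) {
  if (is.numeric(x)) return(as.integer(x))
  v <- which(index$names == x)
  if (length(v) != 1L) stop("unknown species node: ", x, call. = FALSE)
  v
}

resolve_sigma <- function(index, s, sigma) {
  if (index$deg[s] == 0L) return(1L)
  if (is.null(sigma)) return(index$fullmask[s])
  kids <- index$tree$children[[s]]
  idx <- match(vapply(sigma, resolve_node, 1L, index = index), kids)
  if (anyNA(idx)) stop("sigma set contains non-children of the node",
                       call. = FALSE)
  sum(bitwShiftL(1L, idx - 1L))
}

# Scalar event classification on bitmask sigma sets.  Returns NA_integer_
# for invalid candidates (child above s, or both children horizontal).
classify_event_code <- function(index, s, s1, m1, s2, m2) {
  a1 <- inherit_mask(index, s, s1, m1)
  a2 <- inherit_mask(index, s, s2, m2)
  if (is.null(a1) || is.null(a2)) return(NA_integer_)      # child above s
  if (is.na(a1) && is.na(a2)) return(NA_integer_)          # both horizontal
  if (is.na(a1) || is.na(a2)) {
    A1 <- if (is.na(a1)) 0L else a1; A2 <- if (is.na(a2)) 0L else a2
    if (bitwAnd(A1, A2) != 0L) return(EV_DUP)              # unreachable
    return(EV_TRANS)
  }
  if (bitwAnd(a1, a2) != 0L) return(EV_DUP)
  if (index$is_poly[s]) EV_COAL else EV_SPEC
}

#' Species children that vertically inherit a gene child's descendants
#'
#' The sigma set of the duplication test: given a gene node assigned to
#' species `s` and one of its children assigned to `s_child` (with its
#' own vertical-inheritance set when `s_child == s`), returns which
#' children of `s` inherit descendants of that gene child through
#' vertical descent.  A child in a lineage incomparable to `s` is
#' horizontal and inherits nothing vertically (empty set).
#'
#' @param index A `species_index`.
#' @param s Parent assignment (name or id).
#' @param s_child Child assignment (name or id).
#' @param sigma_child Vertical-inheritance set at the child (character
#'   vector of child labels of `s_child`), used when `s_child == s`.
#' @return Character vector of child labels of `s` (empty for a
#'   horizontal child; the species itself when `s` is a leaf).
#' @export
inherited_lineages <- function(index, s, s_child, sigma_child = NULL) {
  s <- resolve_node(index, s); sc <- resolve_node(index, s_child)
  mask <- resolve_sigma(index, sc, sigma_child)
  a <- inherit_mask(index, s, sc, mask)
  if (is.null(a))
    stop("child assignment lies above the parent assignment",
         call. = FALSE)
  if (is.na(a)) return(character(0))
  if (index$deg[s] == 0L) return(index$names[s])
  index$names[mask_children(index, s, a)]
}

# sigma relative to s for a child assigned (sc, mask): the children of s
# that vertically inherit descendants of the gene child.  NULL = invalid
# (sc strictly above s); NA = horizontal (excluded from inheritance).
inherit_mask <- function(index, s, sc, mask) {
  if (sc == s) return(mask)
  if (index$anc[s, sc]) return(index$pathbit[sc, s])
  if (index$anc[sc, s]) return(NULL)
  NA_integer_
}

#' Losses implied along one gene-tree edge
#'
#' Walks the species-tree path implied by a parent context and a child
#' assignment and emits one loss record per bypassed lineage: at a binary
#' species node whose other child does not inherit, a loss in that sibling
#' lineage; at a polytomy with incomplete coverage, a single loss labelled
#' with the whole uncovered child set (any uncovered subset is consistent
#' with a binary resolution and can be lost as a unit).  Entry semantics
#' depend on the parent event: a co-divergence (speciation or coalescence)
#' distributes copies directly into child lineages of `s`, so the walk
#' starts below `s`; a duplication copy, or the vertically inherited child
#' of a transfer, must itself traverse the divergence at `s`; a
#' horizontally transferred child is charged only for incomplete coverage
#' at the recipient.
#'
#' Incomplete coverage at the end of the walk is charged only when the
#' child node's own divergence is a co-divergence there (`child_codiv`):
#' a duplication or transfer at the child happens on the branch above its
#' species, before the radiation, and its copies are charged for crossing
#' it on their own edges instead.
#'
#' @param index A `species_index`.
#' @param event Parent event (`"speciation"`, `"coalescence"`,
#'   `"duplication"`, `"transfer"`).
#' @param s Parent species assignment (name or id).
#' @param s_child Child species assignment (name or id).
#' @param sigma_child Vertical-inheritance set at the child (character
#'   vector of child labels of `s_child`; default full coverage).
#' @param horizontal Is this edge the horizontal (transferred) child?
#' @param child_codiv Is the child's own event a speciation or deep
#'   coalescence at its assignment (default TRUE)?
#' @return A tibble with one row per loss: `species` (node at which the
#'   loss is charged), `label` (lost lineage, or comma-joined uncovered
#'   clade at a polytomy) and `kind` (`"lineage"` or `"clade"`).
#' @export
count_losses <- function(index, event, s, s_child, sigma_child = NULL,
                         horizontal = FALSE, child_codiv = TRUE) {
  s <- resolve_node(index, s); sc <- resolve_node(index, s_child)
  mask <- resolve_sigma(index, sc, sigma_child)
  ev <- match.arg(event, EV_LABELS)
  loss_records(index, match(ev, EV_LABELS), s, sc, mask, horizontal,
               child_codiv)
}

# Internal record walk; nrow() always equals the arithmetic loss count
# used in the DP hot loop.
loss_records <- function(index, event, s, sc, mask, horizontal,
                         child_codiv = TRUE) {
  species <- character(0); label <- character(0); kind <- character(0)
  emit <- function(v, covmask) {
    if (index$deg[v] == 0L) return()
    full <- index$fullmask[v]
    if (bitwAnd(covmask, full) == full) return()
    unc <- mask_children(index, v, bitwAnd(bitwNot(covmask), full))
    if (index$is_poly[v]) {
      species <<- c(species, index$names[v])
      label <<- c(label, paste(sort(index$names[unc]), collapse = ","))
      kind <<- c(kind, "clade")
    } else {
      species <<- c(species, rep(index$names[v], length(unc)))
      label <<- c(label, index$names[unc])
      kind <<- c(kind, rep("lineage", length(unc)))
    }
  }
  if (horizontal) {
    if (child_codiv) emit(sc, mask)
  } else {
    # path s = v0 > v1 > ... > vm = sc
    path <- path_nodes(index, s, sc)
    process <- if (event %in% c(EV_SPEC, EV_COAL)) path[-1L] else path
    for (v in process) {
      if (v == sc) { if (child_codiv) emit(v, mask) }
      else emit(v, index$pathbit[sc, v])
    }
  }
  tibble::tibble(species = species, label = label, kind = kind)
}

# Node path from ancestor s down to descendant sc, inclusive.
path_nodes <- function(index, s, sc) {
  stopifnot(index$anc[s, sc])
  path <- sc; v <- sc
  while (v != s) { v <- index$tree$parent[v]; path <- c(v, path) }
  path
}

#' Score of one candidate event at a gene node
#'
#' The weighted event cost plus the children's subproblem costs plus the
#' loss penalty on the two child edges.  Under the loss-free variants (DT,
#' DTI) the loss term is excluded from the score, although losses are
#' still reconstructed for reporting.
#'
#' @param event Event name.
#' @param child_costs Numeric vector of the two child subproblem scores.
#' @param n_losses Numeric vector of per-child-edge loss counts.
#' @param costs A [cost_scheme()].
#' @param losses_in_score Include the loss penalty (default TRUE)?
#' @return The candidate score.
#' @export
candidate_cost <- function(event, child_costs, n_losses, costs,
                           losses_in_score = TRUE) {
  ev <- match(match.arg(event, EV_LABELS), EV_LABELS)
  lam <- if (losses_in_score) costs$lambda else 0
  event_kappa(ev, costs) + sum(child_costs) + lam * sum(n_losses)
}

#' First pass: the reconciliation dynamic program
#'
#' Visits the gene tree in post-order.  At each internal node, every pair
#' of reachable child table entries (species assignment plus
#' vertical-inheritance subset) is combined with every candidate species
#' assignment `s`; the implied event is classified, edge losses are
#' counted, and the candidate score is accumulated into the node's cost
#' table keyed by `(s, sigma)`.  All ties are retained, so the tables
#' encode every optimal history.
#'
#' @param tg Rooted binary gene `recon_tree`.
#' @param ts Species `recon_tree` or a prebuilt `species_index`.
#' @param map A `leaf_mapping` (see [read_leaf_mapping()]).
#' @param costs A [cost_scheme()].
#' @param model One of `"DT"`, `"DTI"`, `"DTL"`, `"DTLI"`.  Variants
#'   without the I require a fully binary species tree; variants without
#'   the L exclude losses from the optimisation criterion.
#' @return A `dtli_dp` object: optimal score `score`, number of optimal
#'   histories `n_histories`, the optimal root assignments `root_keys`,
#'   and the filled tables consumed by [second_pass()].
#' @export
first_pass <- function(tg, ts, map, costs, model = "DTLI") {
  stopifnot(inherits(tg, "recon_tree"), tg$role == "gene",
            inherits(costs, "cost_scheme"))
  index <- if (inherits(ts, "species_index")) ts else build_species_index(ts)
  mi <- model_info(model)
  if (!mi$allows_polytomy && index$n_poly > 0L)
    stop("model ", mi$model, " requires a binary species tree; ",
         "resolve the polytomies or choose an I-variant (DTI/DTLI)",
         call. = FALSE)
  lam <- if (mi$losses_in_score) costs$lambda else 0
  nS <- index$n
  anc <- index$anc
  po <- postorder_ids(tg$children, tg$root)

  keys <- vector("list", tg$n)   # data.table: s, mask, cost, count, term
  cands <- vector("list", tg$n)  # data.table: s, mask, i1, i2, event, nl1, nl2

  # Table keys are (s, sigma-mask, cdv) where cdv records whether the
  # node's own event is a co-divergence: the loss charged for crossing
  # the divergence at s with incomplete coverage falls on the incoming
  # edge for co-divergence nodes (their divergence IS the radiation),
  # but on the outgoing copy edges for duplication/transfer nodes (their
  # divergence precedes it), so parents must price the two differently.
  for (g in po) {
    if (tg$is_leaf[g]) {
      s <- map[g]
      if (is.na(s)) stop("gene leaf without species mapping: ",
                         tg$label[g], call. = FALSE)
      keys[[g]] <- data.table::data.table(
        s = s, mask = if (index$deg[s] == 0L) 1L else index$fullmask[s],
        cdv = FALSE, cost = 0, count = 1, prop = FALSE)
      next
    }
    ch <- tg$children[[g]]
    k1 <- keys[[ch[1]]]; k2 <- keys[[ch[2]]]
    K1 <- nrow(k1); K2 <- nrow(k2)
    grid <- data.table::CJ(i1 = seq_len(K1), i2 = seq_len(K2),
                           s = seq_len(nS))
    s  <- grid$s
    s1 <- k1$s[grid$i1]; m1 <- k1$mask[grid$i1]
    s2 <- k2$s[grid$i2]; m2 <- k2$mask[grid$i2]
    vert1 <- anc[cbind(s, s1)]; vert2 <- anc[cbind(s, s2)]
    above1 <- !vert1 & anc[cbind(s1, s)]
    above2 <- !vert2 & anc[cbind(s2, s)]
    hor1 <- !vert1 & !above1; hor2 <- !vert2 & !above2
    ok <- !above1 & !above2 & !(hor1 & hor2)
    if (!any(ok)) next
    grid <- grid[ok]; s <- s[ok]
    s1 <- s1[ok]; m1 <- m1[ok]; s2 <- s2[ok]; m2 <- m2[ok]
    hor1 <- hor1[ok]; hor2 <- hor2[ok]
    # vertical-inheritance masks relative to s
    A1 <- ifelse(hor1, 0L, ifelse(s1 == s, m1, index$pathbit[cbind(s1, s)]))
    A2 <- ifelse(hor2, 0L, ifelse(s2 == s, m2, index$pathbit[cbind(s2, s)]))
    event <- ifelse(bitwAnd(A1, A2) != 0L, EV_DUP,
             ifelse(hor1 | hor2, EV_TRANS,
             ifelse(index$is_poly[s], EV_COAL, EV_SPEC)))
    codiv <- event == EV_SPEC | event == EV_COAL
    dd1 <- index$depth[s1] - index$depth[s]
    dd2 <- index$depth[s2] - index$depth[s]
    # terminal coverage charge: only for co-divergence children with a
    # proper subset, and never when a co-divergence parent hands copies
    # directly into the same node's lineages (the lineage-sorting case)
    tc1 <- k1$cdv[grid$i1] & k1$prop[grid$i1] & !(codiv & s1 == s)
    tc2 <- k2$cdv[grid$i2] & k2$prop[grid$i2] & !(codiv & s2 == s)
    nl1 <- ifelse(hor1, 0L, ifelse(codiv, pmax(dd1 - 1L, 0L), dd1)) +
      as.integer(tc1)
    nl2 <- ifelse(hor2, 0L, ifelse(codiv, pmax(dd2 - 1L, 0L), dd2)) +
      as.integer(tc2)
    cost <- event_kappa(event, costs) +
      k1$cost[grid$i1] + k2$cost[grid$i2] + lam * (nl1 + nl2)
    cnt <- k1$count[grid$i1] * k2$count[grid$i2]
    dt <- data.table::data.table(
      s = s, mask = bitwOr(A1, A2), cdv = codiv,
      i1 = grid$i1, i2 = grid$i2,
      event = event, nl1 = nl1, nl2 = nl2, cost = cost, cnt = cnt)
    best <- dt[, list(cost = min(cost)), by = c("s", "mask", "cdv")]
    dt <- dt[best, on = c("s", "mask", "cdv")][cost <= i.cost + COST_EPS]
    dt[, "i.cost" := NULL]
    data.table::setorderv(dt, c("s", "mask", "cdv", "i1", "i2"))
    kk <- dt[, list(cost = min(cost), count = sum(cnt)),
             by = c("s", "mask", "cdv")]
    kk[, "prop" := index$deg[kk$s] != 0L & kk$mask != index$fullmask[kk$s]]
    data.table::setorderv(kk, c("s", "mask", "cdv"))
    keys[[g]] <- kk
    cands[[g]] <- dt
  }

  rk <- keys[[tg$root]]
  if (is.null(rk) || nrow(rk) == 0L)
    stop("no valid reconciliation found (internal error)", call. = FALSE)
  opt <- min(rk$cost)
  root_keys <- rk[rk$cost <= opt + COST_EPS, ]
  structure(
    list(score = opt, n_histories = sum(root_keys$count),
         root_keys = root_keys, keys = keys, cands = cands,
         tg = tg, index = index, map = map, costs = costs,
         model = mi$model, losses_in_score = mi$losses_in_score),
    class = "dtli_dp")
}

#' @export
print.dtli_dp <- function(x, ...) {
  cat(sprintf(
    "<dtli_dp model=%s  optimal score %.6g, %g optimal histor%s>\n",
    x$model, x$score, x$n_histories,
    if (x$n_histories == 1) "y" else "ies"))
  invisible(x)
}
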