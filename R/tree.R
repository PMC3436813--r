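#' @importFrom rlang .data
#' @importFrom stats rpois sd setNames
#' @importFrom utils head tail
#' @importFrom data.table data.table CJ setorderv :=
NULL

# Internal rooted-tree representation
# -----------------------------------
# Nodes carry stable integer ids assigned in deterministic post-order
# (children visited in input order), so that identical Newick input always
# yields identical ids and therefore bit-identical downstream output.
# Fields: n, parent (NA at root), children (list of ordered integer
# vectors), label, is_leaf, root, role ("gene"|"species"), depth (root 0).

new_recon_tree <- function(parent, children, label, role) {
  n <- length(parent)
  is_leaf <- lengths(children) == 0L
  root <- which(is.na(parent))
  stopifnot(length(root) == 1L)
  depth <- integer(n)
  # preorder fill
  ord <- rev(postorder_ids(children, root))
  for (v in ord) depth[v] <- if (is.na(parent[v])) 0L else depth[parent[v]] + 1L
  structure(
    list(n = n, parent = parent, children = children, label = label,
         is_leaf = is_leaf, root = root, role = role, depth = depth),
    class = "recon_tree"
  )
}

postorder_ids <- function(children, root) {
  out <- integer(0)
  walk <- function(v) {
    for (c in children[[v]]) walk(c)
    out[[length(out) + 1L]] <<- v
  }
  walk(root)
  out
}

# Renumber nodes so id == post-order rank; returns an equivalent tree.
canonicalize_ids <- function(parent, children, label, role) {
  root <- which(is.na(parent))
  po <- postorder_ids(children, root)
  newid <- integer(length(parent))
  newid[po] <- seq_along(po)
  np <- integer(length(parent)); nc <- vector("list", length(parent))
  nl <- character(length(parent))
  for (v in seq_along(parent)) {
    w <- newid[v]
    np[w] <- if (is.na(parent[v])) NA_integer_ else newid[parent[v]]
    nc[[w]] <- newid[children[[v]]]
    nl[w] <- label[v]
  }
  new_recon_tree(np, nc, nl, role)
}

#' Parse a Newick string into a rooted tree
#'
#' Branch lengths, comments and quoted labels are accepted and ignored by
#' the reconciliation algorithm, which is purely topological.  Internal
#' node labels are preserved.  Gene trees must be strictly binary; species
#' trees may contain polytomies (internal nodes with more than two
#' children).
#'
#' @param text A Newick string (must end with `;`).
#' @param role Either `"gene"` or `"species"`; controls which arity
#'   invariant is enforced.
#' @return A `recon_tree` object with stable post-order integer node ids.
#' @examples
#' parse_newick("(a,(b,c,d));", "species")
#' parse_newick("((a,b),(c,d));", "gene")
#' @export
parse_newick <- function(text, role = c("gene", "species")) {
  role <- match.arg(role)
  check_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(phy)) stop("Newick parse error: unparseable string", call. = FALSE)
  tr <- tree_from_phylo(phy, role)
  validate_tree(tr)
  tr
}

# Cheap syntactic pre-pass so errors can name a position (ape does not).
check_newick_syntax <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error at position ", i, ": unmatched ')'",
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("Newick parse error at position ", nchar(text),
         ": ", depth, " unclosed '('", call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("Newick parse error at position ", nchar(text),
         ": missing terminal ';'", call. = FALSE)
  invisible(TRUE)
}

tree_from_phylo <- function(phy, role) {
  ntip <- length(phy$tip.label)
  if (is.null(phy$edge)) { # single-leaf degenerate tree
    return(new_recon_tree(NA_integer_, list(integer(0)),
                          phy$tip.label, role))
  }
  n <- ntip + phy$Nnode
  parent <- rep(NA_integer_, n)
  children <- replicate(n, integer(0), simplify = FALSE)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  label <- rep(NA_character_, n)
  label[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label
    lab[!nzchar(lab)] <- NA_character_
    label[ntip + seq_along(lab)] <- lab
  }
  canonicalize_ids(parent, children, label, role)
}

validate_tree <- function(tr) {
  deg <- lengths(tr$children)
  internal <- !tr$is_leaf
  if (tr$role == "gene" && any(deg[internal] != 2L))
    stop("gene tree must be binary: internal node(s) with out-degree ",
         paste(unique(deg[internal][deg[internal] != 2L]), collapse = ","),
         call. = FALSE)
  if (tr$role == "species" && any(deg[internal] < 2L))
    stop("species tree has an internal node with a single child",
         call. = FALSE)
  leaves <- tr$label[tr$is_leaf]
  if (anyNA(leaves) || anyDuplicated(leaves))
    stop("leaf labels must be present and unique", call. = FALSE)
  invisible(tr)
}

#' Write a rooted tree as Newick
#'
#' @param tree A `recon_tree`.
#' @return A Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  fmt <- function(v) {
    if (tree$is_leaf[v]) return(tree$label[v])
    inner <- paste(vapply(tree$children[[v]], fmt, ""), collapse = ",")
    lab <- if (is.na(tree$label[v])) "" else tree$label[v]
    paste0("(", inner, ")", lab)
  }
  paste0(fmt(tree$root), ";")
}

#' @export
print.recon_tree <- function(x, ...) {
  cat(sprintf("<recon_tree role=%s  %d nodes, %d leaves>\n  %s\n",
              x$role, x$n, sum(x$is_leaf), write_newick(x)))
  invisible(x)
}

# Convert to an ape phylo (used for rerooting in root_search).
as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

#' Leaf labels of a tree
#'
#' @param tree A `recon_tree`.
#' @return Character vector of leaf labels.
#' @export
leaf_labels <- function(tree) tree$label[tree$is_leaf]

node_by_label <- function(tree, labels) {
  idx <- match(labels, tree$label)
  if (anyNA(idx))
    stop("unknown node label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

# Human-readable name for any node (internal nodes fall back to the sorted
# leaf-set cluster, so output is stable without requiring internal labels).
node_names <- function(tree) {
  nm <- tree$label
  for (v in postorder_ids(tree$children, tree$root)) {
    if (is.na(nm[v])) {
      tips <- sort(tree$label[tree$is_leaf & descends_from(tree, v)])
      nm[v] <- paste(tips, collapse = "+")
    }
  }
  nm
}

descends_from <- function(tree, v) {
  out <- logical(tree$n)
  stack <- v
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    out[x] <- TRUE
    stack <- c(stack, tree$children[[x]])
  }
  out
}

# SpeciesIndex
# ------------

#' Precompute ancestry machinery for a species tree
#'
#' Builds the all-pairs lca table, ancestry/incomparability predicates,
#' per-node child bitmask conventions and the summary quantities used by
#' the reconciliation dynamic program: tree height `h` (edges, root to
#' deepest leaf), the largest out-degree `kstar` and the number of
#' polytomies `n_poly`.  Vertical-inheritance subsets of a node's children
#' are represented as integer bitmasks (bit i = i-th child); at a species
#' leaf the mask `1` denotes the leaf itself.
#'
#' Because the dynamic program enumerates all nonempty child subsets of
#' every polytomy, its table size grows as `2^kstar`; species trees with
#' `kstar > 12` are refused unless `force = TRUE`.
#'
#' @param ts A species `recon_tree`.
#' @param force Allow very large polytomies (out-degree > 12).
#' @return A `species_index` list; see details.
#' @export
build_species_index <- function(ts, force = FALSE) {
  stopifnot(inherits(ts, "recon_tree"), ts$role == "species")
  n <- ts$n
  deg <- lengths(ts$children)
  kstar <- max(deg)
  if (kstar > 12 && !force)
    stop("species tree has a polytomy of out-degree ", kstar,
         " (> 12); table size grows as 2^k. Use force = TRUE to override.",
         call. = FALSE)
  # anc[u, v] : u is an ancestor of v (reflexive)
  anc <- matrix(FALSE, n, n)
  for (v in seq_len(n)) {
    u <- v
    while (!is.na(u)) { anc[u, v] <- TRUE; u <- ts$parent[u] }
  }
  # lca by root-path intersection (|V|^2 h; species trees are small)
  lca <- matrix(0L, n, n)
  for (u in seq_len(n)) for (v in seq_len(u)) {
    a <- u
    while (!(anc[a, v])) a <- ts$parent[a]
    lca[u, v] <- a; lca[v, u] <- a
  }
  # child rank bit of v within parent's child list
  childbit <- integer(n)
  for (p in which(!ts$is_leaf)) {
    kids <- ts$children[[p]]
    childbit[kids] <- bitwShiftL(1L, seq_along(kids) - 1L)
  }
  # pathbit[v, s]: bitmask (within C(s)) of the child of s on the path to v,
  # defined for strict descendants v < s.
  pathbit <- matrix(0L, n, n)
  pathchild <- matrix(NA_integer_, n, n)
  for (v in seq_len(n)) {
    c <- v; p <- ts$parent[v]
    while (!is.na(p)) {
      pathbit[v, p] <- childbit[c]
      pathchild[v, p] <- c
      c <- p; p <- ts$parent[p]
    }
  }
  fullmask <- ifelse(deg == 0L, 1L, bitwShiftL(1L, deg) - 1L)
  structure(
    list(tree = ts, n = n, deg = deg, anc = anc, lca = lca,
         childbit = childbit, pathbit = pathbit, pathchild = pathchild,
         fullmask = fullmask, depth = ts$depth,
         h = max(ts$depth), kstar = kstar,
         n_poly = sum(deg > 2L),
         is_poly = deg > 2L,
         names = node_names(ts)),
    class = "species_index"
  )
}

#' @export
print.species_index <- function(x, ...) {
  cat(sprintf("<species_index  %d nodes, h=%d, k*=%d, %d polytomies>\n",
              x$n, x$h, x$kstar, x$n_poly))
  invisible(x)
}

# ancestry predicates -------------------------------------------------------

is_ancestor <- function(index, u, v) index$anc[u, v]          # u >= v
is_strict_ancestor <- function(index, u, v) u != v & index$anc[u, v]
is_incomparable <- function(index, u, v) !index$anc[u, v] & !index$anc[v, u]
lca_of <- function(index, u, v) index$lca[u, v]

# nonempty child subsets of s, as bitmasks (C(s)^+ minus the empty set)
child_subsets <- function(index, s) {
  if (index$deg[s] == 0L) return(1L)   # leaf: the "self" mask
  seq_len(index$fullmask[s])
}

# decode a sigma bitmask at species node s into child node ids
mask_children <- function(index, s, mask) {
  if (index$deg[s] == 0L) return(integer(0))
  kids <- index$tree$children[[s]]
  kids[bitwAnd(bitwShiftL(1L, seq_along(kids) - 1L), mask) != 0L]
}

mask_label <- function(index, s, mask) {
  if (index$deg[s] == 0L) return(index$names[s])
  paste(sort(index$names[mask_children(index, s, mask)]), collapse = ",")
}

# LeafMapping
# -----------

#' Read or construct a gene-leaf to species-leaf mapping
#'
#' The mapping is total on gene leaves, need not be injective (paralogous
#' copies in one species are allowed) and need not be surjective.
#'
#' @param x Either a path to a two-column tab-separated file
#'   (gene leaf, species leaf; no header) or a data frame with those two
#'   columns.
#' @param tg,ts Gene and species `recon_tree`s.
#' @return A `leaf_mapping`: integer vector of length `tg$n` giving, for
#'   every gene leaf, the species-tree node id it maps to (NA at internal
#'   gene nodes), with the underlying pair table as attribute `"table"`.
#' @export
read_leaf_mapping <- function(x, tg, ts) {
  if (is.character(x) && length(x) == 1L) {
    df <- utils::read.table(x, sep = "\t", header = FALSE,
                            col.names = c("gene", "species"),
                            colClasses = "character")
  } else {
    df <- as.data.frame(x)[, 1:2]
    names(df) <- c("gene", "species")
  }
  make_leaf_mapping(df$gene, df$species, tg, ts)
}

#' Derive a leaf mapping from a gene-leaf naming convention
#'
#' Gene leaves named `<gene>SEP<species>` (species suffix after the last
#' separator) are mapped to the species leaf of that name.
#'
#' @param tg,ts Gene and species trees.
#' @param sep Separator string (default `"_"`).
#' @export
leaf_map_from_names <- function(tg, ts, sep = "_") {
  genes <- leaf_labels(tg)
  sp <- sub(paste0("^.*", sep), "", genes)
  make_leaf_mapping(genes, sp, tg, ts)
}

make_leaf_mapping <- function(gene, species, tg, ts) {
  gl <- leaf_labels(tg); sl <- leaf_labels(ts)
  if (anyDuplicated(gene))
    stop("duplicated gene leaf in mapping: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "),
         call. = FALSE)
  missing_g <- setdiff(gl, gene)
  if (length(missing_g))
    stop("gene leaves missing from mapping: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  unknown_g <- setdiff(gene, gl)
  if (length(unknown_g))
    stop("mapping names unknown gene leaves: ",
         paste(unknown_g, collapse = ", "), call. = FALSE)
  bad_s <- setdiff(species, sl)
  if (length(bad_s))
    stop("mapping names species absent from the species tree: ",
         paste(bad_s, collapse = ", "), call. = FALSE)
  map <- rep(NA_integer_, tg$n)
  map[node_by_label(tg, gene)] <- node_by_label(ts, species)
  structure(map, class = "leaf_mapping",
            table = tibble::tibble(gene = gene, species = species))
}

# collapse_edge
# -------------

#' Collapse an internal edge of a species tree into a polytomy
#'
#' The edge is identified by the label (or cluster name, see
#' [parse_newick()]) of its child node; the child is removed and its
#' children promoted to the parent, in place, growing a polytomy.  Used to
#' mark lineages where incomplete lineage sorting should be entertained.
#'
#' @param ts A species `recon_tree`.
#' @param child The child node of the edge to collapse: either an integer
#'   node id or a node name as produced by `node_names()` (a label, or the
#'   `+`-joined sorted leaf cluster for unlabeled internals).
#' @return A new species `recon_tree` with one fewer node, same leaf set.
#' @examples
#' ts <- parse_newick("(a,(b,(c,d)));", "species")
#' write_newick(collapse_edge(ts, "c+d"))  # "(a,(b,c,d));"
#' @export
collapse_edge <- function(ts, child) {
  stopifnot(inherits(ts, "recon_tree"), ts$role == "species")
  v <- if (is.numeric(child)) as.integer(child)
       else which(node_names(ts) == child)
  if (length(v) != 1L || is.na(v) || v < 1L || v > ts$n)
    stop("cannot identify edge child node: ", child, call. = FALSE)
  if (ts$is_leaf[v]) stop("cannot collapse a leaf edge", call. = FALSE)
  p <- ts$parent[v]
  if (is.na(p)) stop("cannot collapse the root", call. = FALSE)
  keep <- setdiff(seq_len(ts$n), v)
  parent <- ts$parent; children <- ts$children
  # splice v's children into p's child list at v's position
  pos <- match(v, children[[p]])
  children[[p]] <- append(setdiff(children[[p]], v),
                          children[[v]], after = pos - 1L)
  parent[children[[v]]] <- p
  # reindex over kept nodes
  newid <- match(seq_len(ts$n), keep)
  np <- parent[keep]; np <- ifelse(is.na(np), NA_integer_, newid[np])
  nc <- lapply(children[keep], function(k) newid[k])
  canonicalize_ids(np, nc, ts$label[keep], "species")
}
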