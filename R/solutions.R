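# Second pass: enumerate every optimal history from the DP tables and
# materialise fully annotated reconciliations.

#' Enumerate all optimal reconciliation histories
#'
#' Traces back through the tables filled by [first_pass()], visiting every
#' tied candidate, and returns each optimal history exactly once.  A
#' history is identified by the species assignment of every gene node
#' (events, transfer edges and loss records are all determined by that
#' assignment), so the number of enumerated histories equals the count
#' reported by the first pass unless the cap is hit.
#'
#' @param dp A `dtli_dp` object from [first_pass()].
#' @param max_histories Enumeration cap; counts remain exact even when the
#'   enumeration is truncated (the `truncated` flag is then set).
#' @return A `dtli_solutions` object: `score`, `n_optimal` (exact count),
#'   a list `histories` of `dtli_history` annotations, and bookkeeping
#'   flags.  Feasibility flags are NA until [filter_feasible()] runs.
#' @export
second_pass <- function(dp, max_histories = 10000) {
  stopifnot(inherits(dp, "dtli_dp"))
  tg <- dp$tg; index <- dp$index
  cache <- new.env(parent = emptyenv())
  truncated <- FALSE

  # Returns a list of assignments for the subtree at g given table key
  # (s, mask); each assignment is a list(M=int vec, mask=int vec) indexed
  # by gene node id (NA outside the subtree).
  enum <- function(g, s, mask, cdv) {
    kid <- paste(g, s, mask, cdv, sep = ":")
    hit <- cache[[kid]]
    if (!is.null(hit)) return(hit)
    if (tg$is_leaf[g]) {
      M <- rep(NA_integer_, tg$n); Sm <- rep(NA_integer_, tg$n)
      M[g] <- s; Sm[g] <- mask
      res <- list(list(M = M, mask = Sm))
    } else {
      cd <- dp$cands[[g]]
      rows <- which(cd$s == s & cd$mask == mask & cd$cdv == cdv)
      if (!length(rows))
        stop("corrupted DP tables: no candidate at a reachable key",
             call. = FALSE)
      ch <- tg$children[[g]]
      k1 <- dp$keys[[ch[1]]]; k2 <- dp$keys[[ch[2]]]
      res <- list()
      for (r in rows) {
        sub1 <- enum(ch[1], k1$s[cd$i1[r]], k1$mask[cd$i1[r]],
                     k1$cdv[cd$i1[r]])
        sub2 <- enum(ch[2], k2$s[cd$i2[r]], k2$mask[cd$i2[r]],
                     k2$cdv[cd$i2[r]])
        for (a in sub1) {
          for (b in sub2) {
            M <- ifelse(is.na(a$M), b$M, a$M)
            Sm <- ifelse(is.na(a$mask), b$mask, a$mask)
            M[g] <- s; Sm[g] <- mask
            res[[length(res) + 1L]] <- list(M = M, mask = Sm)
            if (length(res) >= max_histories) break
          }
          if (length(res) >= max_histories) break
        }
        if (length(res) >= max_histories) break
      }
    }
    cache[[kid]] <- res
    res
  }

  assigns <- list()
  rk <- dp$root_keys
  for (r in seq_len(nrow(rk))) {
    for (a in enum(tg$root, rk$s[r], rk$mask[r], rk$cdv[r])) {
      if (length(assigns) >= max_histories) { truncated <- TRUE; break }
      assigns[[length(assigns) + 1L]] <- a
    }
    if (truncated) break
  }
  if (dp$n_histories > length(assigns)) truncated <- TRUE

  histories <- lapply(assigns, function(a)
    materialize_history(dp, a$M, a$mask))
  structure(
    list(score = dp$score, n_optimal = dp$n_histories,
         histories = histories, truncated = truncated,
         feasible = rep(NA, length(histories)), status = "unfiltered",
         model = dp$model, costs = dp$costs,
         losses_in_score = dp$losses_in_score,
         tg = tg, index = index, map = dp$map),
    class = "dtli_solutions")
}

# Build the full annotation of one history from its assignment vector.
materialize_history <- function(dp, M, mask) {
  tg <- dp$tg; index <- dp$index
  n <- tg$n
  event <- rep(NA_integer_, n)
  horizontal <- rep(FALSE, n)   # indexed by child node of the edge
  gnames <- node_names(tg)
  for (g in which(!tg$is_leaf)) {
    ch <- tg$children[[g]]
    horizontal[ch] <- is_incomparable(index, M[g], M[ch])
    event[g] <- classify_event_code(index, M[g],
                                    M[ch[1]], mask[ch[1]],
                                    M[ch[2]], mask[ch[2]])
  }
  loss <- list()
  for (g in which(!tg$is_leaf)) {
    for (c in tg$children[[g]]) {
      rec <- loss_records(index, event[g], M[g], M[c], mask[c],
                          horizontal[c],
                          child_codiv = !tg$is_leaf[c] &&
                            event[c] %in% c(EV_SPEC, EV_COAL))
      if (nrow(rec))
        loss[[length(loss) + 1L]] <- cbind(gene_edge = gnames[c], rec)
    }
  }
  losses <- if (length(loss))
    tibble::as_tibble(do.call(rbind, loss))
  else tibble::tibble(gene_edge = character(0),
                      species = character(0),
                      label = character(0), kind = character(0))
  tr_child <- which(horizontal)
  transfers <- tibble::tibble(
    gene_node = gnames[tg$parent[tr_child]],
    gene_child = gnames[tr_child],
    donor = index$names[M[tg$parent[tr_child]]],
    recipient = index$names[M[tr_child]])
  nodes <- tibble::tibble(
    node = seq_len(n), name = gnames,
    is_leaf = tg$is_leaf,
    species = index$names[M],
    event = ifelse(is.na(event), NA_character_, EV_LABELS[event]))
  h <- structure(
    list(nodes = nodes, losses = losses, transfers = transfers,
         M = M, mask = mask, event = event, horizontal = horizontal,
         tg = tg, index = index),
    class = "dtli_history")
  h$score <- score_history(h, dp$costs, dp$losses_in_score)
  h
}

#' @export
print.dtli_history <- function(x, ...) {
  cnt <- history_counts(x)
  cat(sprintf(
    "<dtli_history  score %.6g: %dD %dT %dL %dC %dS>\n",
    x$score, cnt$n_dup, cnt$n_trans, cnt$n_loss, cnt$n_coal, cnt$n_spec))
  invisible(x)
}

history_counts <- function(h) {
  list(n_dup = sum(h$event == EV_DUP, na.rm = TRUE),
       n_trans = sum(h$event == EV_TRANS, na.rm = TRUE),
       n_loss = nrow(h$losses),
       n_coal = sum(h$event == EV_COAL, na.rm = TRUE),
       n_spec = sum(h$event == EV_SPEC, na.rm = TRUE))
}

#' Rescore a history from its annotations
#'
#' Computes the weighted event total (duplications times delta, transfers
#' times tau, losses times lambda) purely from the annotated history,
#' independently of the dynamic-program internals.  Used as a consistency
#' check: every enumerated optimal history must rescore to the DP optimum.
#'
#' @param history A `dtli_history`.
#' @param costs A [cost_scheme()].
#' @param losses_in_score Include the loss term (FALSE for DT/DTI)?
#' @return The history score.
#' @export
score_history <- function(history, costs, losses_in_score = TRUE) {
  cnt <- history_counts(history)
  lam <- if (losses_in_score) costs$lambda else 0
  costs$delta * cnt$n_dup + costs$tau * cnt$n_trans + lam * cnt$n_loss
}

#' Tally events across the optimal histories
#'
#' @param sols A `dtli_solutions` object.
#' @return A `dtli_event_summary` list: `counts` (one row per history:
#'   `n_dup`, `n_trans`, `n_loss`, `n_coal`, `n_spec`, plus the
#'   feasibility flag), `by_species` (event tallies per species lineage,
#'   summed over histories), `transfers` (per donor/recipient pair) and
#'   `degenerate` (TRUE iff two histories disagree in any event count —
#'   the retention rule used for batch reporting).
#' @export
summarize_events <- function(sols) {
  stopifnot(inherits(sols, "dtli_solutions"))
  if (!length(sols$histories)) stop("empty solution set", call. = FALSE)
  counts <- dplyr::bind_rows(lapply(seq_along(sols$histories), function(i) {
    cnt <- history_counts(sols$histories[[i]])
    tibble::tibble(history = i, n_dup = cnt$n_dup, n_trans = cnt$n_trans,
                   n_loss = cnt$n_loss, n_coal = cnt$n_coal,
                   n_spec = cnt$n_spec, feasible = sols$feasible[i])
  }))
  key <- counts[, c("n_dup", "n_trans", "n_loss", "n_coal")]
  degenerate <- nrow(unique(key)) > 1L
  by_species <- dplyr::bind_rows(lapply(sols$histories, function(h) {
    ev <- h$nodes[!is.na(h$nodes$event), c("species", "event")]
    lo <- tibble::tibble(species = h$losses$species, event = "loss")
    dplyr::bind_rows(ev, lo)
  }))
  by_species <- dplyr::count(by_species, .data$species, .data$event,
                             name = "n")
  transfers <- dplyr::bind_rows(lapply(sols$histories,
                                       function(h) h$transfers))
  transfers <- if (nrow(transfers))
    dplyr::count(transfers, .data$donor, .data$recipient, name = "n")
  else tibble::tibble(donor = character(0), recipient = character(0),
                      n = integer(0))
  structure(list(counts = counts, by_species = by_species,
                 transfers = transfers, degenerate = degenerate),
            class = "dtli_event_summary")
}

#' @export
print.dtli_event_summary <- function(x, ...) {
  cat(sprintf("<dtli_event_summary  %d histor%s, degenerate=%s>\n",
              nrow(x$counts), if (nrow(x$counts) == 1) "y" else "ies",
              x$degenerate))
  print(x$counts)
  invisible(x)
}

#' @export
print.dtli_solutions <- function(x, ...) {
  cat(sprintf(
    "<dtli_solutions model=%s  score %.6g, %g optimal histor%s (%d enumerated%s)>\n",
    x$model, x$score, x$n_optimal,
    if (x$n_optimal == 1) "y" else "ies",
    length(x$histories), if (x$truncated) ", truncated" else ""))
  if (x$status == "all_optimal_infeasible")
    cat("  all optimal histories are temporally infeasible\n")
  invisible(x)
}

# Annotated output -----------------------------------------------------------

#' Write a history as NHX-annotated Newick plus an event table
#'
#' Every gene-tree node carries its species assignment (`S=`) and, for
#' internal nodes, the event code (`Ev=` one of D, T, S, C); the child
#' node of each transfer edge is additionally tagged `H=Y` with donor and
#' recipient species.  The companion table has one row per event,
#' including losses with the species or uncovered polytomy clade in which
#' they occurred.
#'
#' @param history A `dtli_history`.
#' @param file Optional path prefix; writes `<file>.nhx` and
#'   `<file>.events.tsv`.
#' @return Invisibly, a list with elements `nhx` (string) and `events`
#'   (tibble).
#' @export
write_annotated_tree <- function(history, file = NULL) {
  h <- history; tg <- h$tg
  evcode <- c("S", "C", "D", "T")
  tag <- function(v) {
    parts <- c(paste0("S=", h$nodes$species[v]))
    if (!tg$is_leaf[v])
      parts <- c(parts, paste0("Ev=", evcode[h$event[v]]))
    if (h$horizontal[v])
      parts <- c(parts, "H=Y",
                 paste0("DON=", h$index$names[h$M[tg$parent[v]]]),
                 paste0("REC=", h$index$names[h$M[v]]))
    paste0("[&&NHX:", paste(parts, collapse = ":"), "]")
  }
  fmt <- function(v) {
    if (tg$is_leaf[v]) return(paste0(tg$label[v], tag(v)))
    inner <- paste(vapply(tg$children[[v]], fmt, ""), collapse = ",")
    paste0("(", inner, ")", tag(v))
  }
  nhx <- paste0(fmt(tg$root), ";")
  gnames <- node_names(tg)
  ev_rows <- lapply(which(!tg$is_leaf), function(v) tibble::tibble(
    type = EV_LABELS[h$event[v]], gene_node = gnames[v],
    species = h$nodes$species[v],
    donor = if (h$event[v] == EV_TRANS)
      h$index$names[h$M[v]] else NA_character_,
    recipient = if (h$event[v] == EV_TRANS)
      h$index$names[h$M[which(h$horizontal & tg$parent == v)]]
    else NA_character_,
    loss_clade = NA_character_))
  loss_rows <- if (nrow(h$losses)) tibble::tibble(
    type = "loss", gene_node = h$losses$gene_edge,
    species = h$losses$species,
    donor = NA_character_, recipient = NA_character_,
    loss_clade = h$losses$label) else NULL
  events <- dplyr::bind_rows(c(ev_rows, list(loss_rows)))
  if (!is.null(file)) {
    writeLines(nhx, paste0(file, ".nhx"))
    utils::write.table(events, paste0(file, ".events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(nhx = nhx, events = events))
}

#' Parse NHX output written by [write_annotated_tree()]
#'
#' A minimal reader for the package's own tag vocabulary; returns the node
#' annotations so that event counts can be reconstructed from a written
#' file.
#'
#' @param text An NHX string (or path to a file containing one).
#' @return A tibble with one row per node: `label`, `species`, `event`,
#'   `horizontal`, `donor`, `recipient`.
#' @export
read_annotated_tree <- function(text) {
  if (file.exists(text)) text <- paste(readLines(text), collapse = "")
  text <- sub(";\\s*$", "", text)
  pos <- 1L
  nchars <- nchar(text)
  peek <- function() substr(text, pos, pos)
  rows <- list()
  parse_node <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        parse_node()
        if (peek() == ",") { pos <<- pos + 1L } else break
      }
      stopifnot(peek() == ")")
      pos <<- pos + 1L
    }
    # label up to '[' or structural char
    lab <- ""
    while (pos <= nchars && !peek() %in% c("[", ",", ")", "(") ) {
      lab <- paste0(lab, peek()); pos <<- pos + 1L
    }
    ann <- character(0)
    if (pos <= nchars && peek() == "[") {
      close <- regexpr("]", substr(text, pos, nchars), fixed = TRUE)
      ann <- substr(text, pos + 1L, pos + close - 2L)
      pos <<- pos + close
    }
    tags <- list()
    if (length(ann) && startsWith(ann, "&&NHX:")) {
      kv <- strsplit(strsplit(sub("^&&NHX:", "", ann), ":")[[1]], "=")
      tags <- setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
    }
    evmap <- c(S = "speciation", C = "coalescence", D = "duplication",
               T = "transfer")
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      label = if (nzchar(lab)) lab else NA_character_,
      species = tags$S %||% NA_character_,
      event = if (!is.null(tags$Ev)) unname(evmap[tags$Ev])
              else NA_character_,
      horizontal = identical(tags$H, "Y"),
      donor = tags$DON %||% NA_character_,
      recipient = tags$REC %||% NA_character_)
    invisible(NULL)
  }
  parse_node()
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
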