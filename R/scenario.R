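# Explicit operation scenarios: every component of a recovered decomposition
# is transformed into a short series of DEL / INS / DCJ rewrites on the
# adjacency set of genome 1, such that replaying all operations turns S1
# into S2. Per component: deletions resolve its T1 ghosts, insertions its
# T2 ghosts, DCJs split what remains into matched 2-cycles / length-1 paths.

new_op <- function(kind, consumed, produced, gene = NA_character_) {
  list(kind = kind, consumed = consumed, produced = produced, gene = gene)
}

drop_one <- function(v, x) {
  i <- match(x, v)
  stopifnot(!is.na(i))
  v[-i]
}

rotate_cycle <- function(chain, k) {
  m <- length(chain$nodes)
  idx <- ((seq_len(m) + k - 2L) %% m) + 1L
  chain$nodes <- chain$nodes[idx]
  chain$edge_labels <- chain$edge_labels[idx]
  chain
}

reverse_chain <- function(chain) {
  m <- length(chain$nodes)
  chain$nodes <- rev(chain$nodes)
  if (chain$kind == "cycle") {
    # edge i connected nodes i and i+1 (mod m); after reversal edge i must
    # connect rev positions: new edge j = old edge m - j
    chain$edge_labels <- chain$edge_labels[c(m - seq_len(m - 1L), m)]
  } else {
    chain$edge_labels <- rev(chain$edge_labels)
  }
  chain
}

node_is <- function(nd, side, ghost = NA) {
  nd$side == side && (is.na(ghost) || nd$ghost == ghost)
}

mk_node <- function(labels, side = "L", ghost = FALSE) {
  list(side = side, labels = labels, ghost = ghost, tel = length(labels) == 1L)
}

# splice [x1, x2, x3] at positions 1..3 of a cycle (or i-1..i+1 of a path)
# down to one replacement node; callers arrange the rotation

#' Operations resolving one component
#'
#' Emits the ordered operations that transform the genome-1 side of a single
#' recovered component into its genome-2 side: first the deletions for its
#' surplus-in-1 ghosts, then the insertions for its surplus-in-2 ghosts,
#' then DCJ operations. A helpful cycle of length l with d + i ghosts costs
#' d + i + l/2 - d - i - 1 operations, an unhelpful cycle l/2, an odd path
#' (l-1)/2, an even path l/2.
#'
#' @param comp A recovered component ("chain") from [recover_uncapped()].
#' @return List of operations (`kind`, `consumed`, `produced`, `gene`).
#' @export
component_operations <- function(comp) {
  chain <- comp
  ops <- list()
  emit <- function(op) ops[[length(ops) + 1L]] <<- op

  # --- phase 1: deletions for right-side (T1) ghosts ---------------------
  repeat {
    gi <- ghost_index(chain, "R")
    if (is.na(gi)) break
    res <- do_deletion(chain, gi)
    emit(res$op)
    chain <- res$chain
    if (is.null(chain)) return(ops)
  }
  # --- phase 2: insertions for left-side (T2) ghosts ---------------------
  repeat {
    gidx <- which(vapply(chain$nodes, node_is, logical(1), side = "L", ghost = TRUE))
    if (!length(gidx)) break
    res <- do_insertion(chain, gidx)
    emit(res$op)
    chain <- res$chain
    if (is.null(chain)) return(ops)
  }
  # --- phase 3: DCJ resolution of the all-real remainder -----------------
  repeat {
    if (is.null(chain)) break
    if (chain$kind == "cycle") {
      if (length(chain$nodes) <= 2L) break
      res <- cycle_dcj(chain)
    } else {
      if (length(chain$edge_labels) <= 1L) break
      res <- path_dcj(chain)
    }
    emit(res$op)
    chain <- res$chain
  }
  ops
}

ghost_index <- function(chain, side) {
  hit <- which(vapply(chain$nodes, node_is, logical(1), side = side, ghost = TRUE))
  if (length(hit)) hit[1L] else NA_integer_
}

nbr <- function(chain, i, dir) {
  m <- length(chain$nodes)
  j <- i + dir
  if (chain$kind == "cycle") ((j - 1L) %% m) + 1L else if (j >= 1L && j <= m) j else NA_integer_
}

edge_between <- function(chain, i, j) {
  # label of the edge from node i to its successor j (j = i+1 circularly)
  m <- length(chain$nodes)
  if (chain$kind == "cycle") {
    if (((i %% m) + 1L) == j) chain$edge_labels[i] else chain$edge_labels[j]
  } else {
    chain$edge_labels[min(i, j)]
  }
}

do_deletion <- function(chain, gi) {
  gene <- ext_gene(chain$nodes[[gi]]$labels[1L])
  ai <- nbr(chain, gi, -1L)
  bi <- nbr(chain, gi, +1L)
  a <- chain$nodes[[ai]]; b <- chain$nodes[[bi]]
  la <- edge_between(chain, ai, gi)
  lb <- edge_between(chain, gi, bi)
  if (!is.na(ai) && !is.na(bi) && ai == bi) {
    # 2-cycle: the single left neighbor carries both extremities
    op <- new_op("DEL", list(a$labels), list(), gene)
    return(list(op = op, chain = NULL))
  }
  merged <- c(drop_one(a$labels, la), drop_one(b$labels, lb))
  op <- new_op("DEL", list(a$labels, b$labels),
               if (length(merged)) list(merged) else list(), gene)
  chain2 <- splice_triple(chain, ai, gi, bi, if (length(merged)) mk_node(merged) else NULL)
  list(op = op, chain = chain2)
}

# replace the three consecutive nodes (ai, mi, bi) by `repl` (or drop them)
splice_triple <- function(chain, ai, mi, bi, repl) {
  m <- length(chain$nodes)
  if (chain$kind == "cycle") {
    chain <- rotate_cycle(chain, ai)
    # now positions 1,2,3; outer edges are edge_labels[3..m] with wrap at m
    if (m <= 3L) {
      return(NULL)  # nothing left (fully consumed)
    }
    nodes <- c(if (!is.null(repl)) list(repl), chain$nodes[4:m])
    edges <- chain$edge_labels[3:m]
    if (is.null(repl)) stop("cycle splice cannot drop its junction", call. = FALSE)
    list(kind = "cycle", nodes = nodes, edge_labels = edges)
  } else {
    keep_before <- if (ai > 1L) seq_len(ai - 1L) else integer(0)
    keep_after <- if (bi < m) (bi + 1L):m else integer(0)
    nodes <- c(chain$nodes[keep_before], if (!is.null(repl)) list(repl),
               chain$nodes[keep_after])
    if (!length(nodes)) return(NULL)
    e_before <- if (ai > 1L) seq_len(ai - 1L) else integer(0)
    e_after <- if (bi < m) bi:(m - 1L) else integer(0)
    edges <- chain$edge_labels[c(e_before, e_after)]
    list(kind = "path", nodes = nodes, edge_labels = edges)
  }
}

do_insertion <- function(chain, gidx) {
  m <- length(chain$nodes)
  # (a) a ghost whose adjacent right element leads on to a real left node
  for (gi in gidx) {
    for (dir in c(1L, -1L)) {
      fi <- nbr(chain, gi, dir)
      if (is.na(fi)) next
      f <- chain$nodes[[fi]]
      if (f$tel) next
      wi <- nbr(chain, fi, dir)
      if (is.na(wi) || wi == gi) next
      w <- chain$nodes[[wi]]
      if (w$ghost) next
      return(insert_via_adjacency(chain, gi, fi, wi, dir))
    }
  }
  # (b) a ghost next to a right telomere endpoint
  for (gi in gidx) {
    for (dir in c(1L, -1L)) {
      fi <- nbr(chain, gi, dir)
      if (is.na(fi)) next
      if (chain$nodes[[fi]]$tel) {
        return(insert_at_telomere(chain, gi, fi, dir))
      }
    }
  }
  # (c) cycle consisting purely of ghosts on the left: bootstrap with a
  # circular single-gene insertion
  gi <- gidx[1L]
  g <- chain$nodes[[gi]]
  op <- new_op("INS", list(), list(g$labels), ext_gene(g$labels[1L]))
  if (length(chain$nodes) == 2L) {
    # 2-cycle against the matching real right adjacency: done
    return(list(op = op, chain = NULL))
  }
  chain$nodes[[gi]]$ghost <- FALSE
  list(op = op, chain = chain)
}

insert_via_adjacency <- function(chain, gi, fi, wi, dir) {
  g <- chain$nodes[[gi]]; f <- chain$nodes[[fi]]; w <- chain$nodes[[wi]]
  gene <- ext_gene(g$labels[1L])
  la <- edge_between(chain, if (dir == 1L) gi else fi, if (dir == 1L) fi else gi)
  lb_other <- drop_one(g$labels, la)          # ghost's far-side extremity
  z <- edge_between(chain, if (dir == 1L) fi else wi, if (dir == 1L) wi else fi)
  produced1 <- c(z, la)                        # equals f's labels
  rest_w <- drop_one(w$labels, z)
  produced2 <- c(rest_w, lb_other)
  op <- new_op("INS", list(w$labels), list(produced1, produced2), gene)
  repl <- mk_node(produced2)
  chain2 <- if (dir == 1L) {
    splice_triple(chain, gi, fi, wi, repl)
  } else {
    splice_triple(chain, wi, fi, gi, repl)
  }
  list(op = op, chain = chain2)
}

insert_at_telomere <- function(chain, gi, fi, dir) {
  g <- chain$nodes[[gi]]
  gene <- ext_gene(g$labels[1L])
  la <- edge_between(chain, min(gi, fi), max(gi, fi))
  lb <- drop_one(g$labels, la)
  oi <- nbr(chain, gi, -dir)                   # the other neighbor
  other_tel <- !is.na(oi) && chain$nodes[[oi]]$tel &&
    length(chain$nodes) == 3L
  op <- new_op("INS", list(), list(la, lb), gene)
  if (other_tel) return(list(op = op, chain = NULL))
  # replace [f, ghost] by the new left telomere {lb}
  m <- length(chain$nodes)
  lo <- min(gi, fi); hi <- max(gi, fi)
  keep_before <- if (lo > 1L) seq_len(lo - 1L) else integer(0)
  keep_after <- if (hi < m) (hi + 1L):m else integer(0)
  nodes <- c(chain$nodes[keep_before], list(mk_node(lb)), chain$nodes[keep_after])
  e_before <- if (lo > 1L) seq_len(lo - 1L) else integer(0)
  e_after <- if (hi < m) hi:(m - 1L) else integer(0)
  edges <- chain$edge_labels[c(e_before, e_after)]
  list(op = op, chain = list(kind = "path", nodes = nodes, edge_labels = edges))
}

cycle_dcj <- function(chain) {
  # rotate a left node to position 1; split the 2-cycle (nodes 1-3 vs 2)
  li <- which(vapply(chain$nodes, node_is, logical(1), side = "L"))[1L]
  chain <- rotate_cycle(chain, li)
  a <- chain$nodes[[1L]]; f <- chain$nodes[[2L]]; b <- chain$nodes[[3L]]
  la <- chain$edge_labels[1L]
  lb <- chain$edge_labels[2L]
  joined <- c(drop_one(a$labels, la), drop_one(b$labels, lb))
  op <- new_op("DCJ", list(a$labels, b$labels), list(f$labels, joined))
  chain2 <- splice_triple(chain, 1L, 2L, 3L, mk_node(joined))
  list(op = op, chain = chain2)
}

path_dcj <- function(chain) {
  # trim from a left-telomere end when possible: that removes two edges per
  # DCJ; the right-end trim below removes only one and is optimal only when
  # both endpoints are right telomeres (even path, one odd-parity flip)
  m <- length(chain$nodes)
  if (chain$nodes[[1L]]$side != "L" && chain$nodes[[m]]$side == "L") {
    chain <- reverse_chain(chain)
  }
  n1 <- chain$nodes[[1L]]
  if (n1$side == "L") {
    # left telomere end {x} against right adjacency {x, y}
    f <- chain$nodes[[2L]]
    e1 <- chain$nodes[[3L]]
    y <- chain$edge_labels[2L]
    rest <- drop_one(e1$labels, y)
    if (!length(rest)) {
      op <- new_op("DCJ", list(n1$labels, e1$labels), list(f$labels))
      return(list(op = op, chain = NULL))
    }
    op <- new_op("DCJ", list(n1$labels, e1$labels), list(f$labels, rest))
    m <- length(chain$nodes)
    nodes <- c(list(mk_node(rest)), chain$nodes[seq_len(m)[-(1:3)]])
    edges <- chain$edge_labels[-(1:2)]
    list(op = op, chain = list(kind = "path", nodes = nodes, edge_labels = edges))
  } else {
    # right telomere end {x}: cut x off the left neighbor
    e <- chain$nodes[[2L]]
    x <- chain$edge_labels[1L]
    rest <- drop_one(e$labels, x)
    op <- new_op("DCJ", list(e$labels), list(n1$labels, rest))
    m <- length(chain$nodes)
    nodes <- c(list(mk_node(rest)), chain$nodes[seq_len(m)[-(1:2)]])
    edges <- chain$edge_labels[-1L]
    list(op = op, chain = list(kind = "path", nodes = nodes, edge_labels = edges))
  }
}

#' Build a full scenario from a distance report
#'
#' Concatenates [component_operations()] over all recovered components of
#' the report in deterministic order and checks the operation-count law:
#' exactly `|T1|` deletions, `|T2|` insertions and a total equal to the
#' reported distance.
#'
#' @param report An [edit_distance()] result.
#' @return A `dcj_scenario`: `ops`, `counts` (named DCJ/INS/DEL), `distance`.
#' @export
build_scenario <- function(report) {
  ops <- list()
  for (comp in report$recovered) {
    ops <- c(ops, component_operations(comp))
  }
  kinds <- vapply(ops, `[[`, character(1), "kind")
  counts <- c(DCJ = sum(kinds == "DCJ"), INS = sum(kinds == "INS"),
              DEL = sum(kinds == "DEL"))
  if (counts[["DEL"]] != report$t1_size || counts[["INS"]] != report$t2_size ||
      length(ops) != report$distance) {
    stop("scenario construction violated the operation-count law ",
         sprintf("(DEL %d/%d, INS %d/%d, total %d/%d)", counts[["DEL"]],
                 report$t1_size, counts[["INS"]], report$t2_size,
                 length(ops), report$distance), call. = FALSE)
  }
  structure(list(ops = ops, counts = counts, distance = report$distance),
            class = "dcj_scenario")
}

#' @export
print.dcj_scenario <- function(x, ...) {
  cat("Edit scenario with", length(x$ops), "operations",
      sprintf("(DCJ %d, INS %d, DEL %d)\n", x$counts[["DCJ"]],
              x$counts[["INS"]], x$counts[["DEL"]]))
  invisible(x)
}

fmt_element <- function(labels) {
  if (!length(labels)) return("-")
  paste(labels, collapse = " ")
}

#' Scenario as a data frame
#'
#' @param x A `dcj_scenario`.
#' @param ... Unused.
#' @return Data frame with step, kind, gene, consumed, produced columns.
#' @export
as.data.frame.dcj_scenario <- function(x, ...) {
  data.frame(
    step = seq_along(x$ops),
    kind = vapply(x$ops, `[[`, character(1), "kind"),
    gene = vapply(x$ops, function(o) o$gene %||% NA_character_, character(1)),
    consumed = vapply(x$ops, function(o) {
      paste(vapply(o$consumed, fmt_element, character(1)), collapse = " + ")
    }, character(1)),
    produced = vapply(x$ops, function(o) {
      paste(vapply(o$produced, fmt_element, character(1)), collapse = " + ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Apply one operation to an adjacency set
#'
#' Removes the consumed elements (which must be present) and adds the
#' produced ones.
#'
#' @param s An [adjacency_set()].
#' @param op An operation (from a scenario, or hand-built with the same
#'   structure).
#' @return The rewritten adjacency set.
#' @export
apply_operation <- function(s, op) {
  els <- s$elements
  keys <- vapply(els, element_key, character(1))
  drop <- integer(0)
  for (cons in op$consumed) {
    k <- paste(sort(cons), collapse = "~")
    hit <- setdiff(which(keys == k), drop)
    if (!length(hit)) {
      stop("operation consumes element not present: ", k, call. = FALSE)
    }
    drop <- c(drop, hit[1L])
  }
  if (length(drop)) els <- els[-drop]
  for (prod in op$produced) {
    els[[length(els) + 1L]] <- if (length(prod) == 1L) {
      telomere(prod)
    } else {
      adjacency(prod[1L], prod[2L])
    }
  }
  adjacency_set(els)
}

#' Check an operation against the rewrite schemas
#'
#' Verifies that the (consumed, produced) pair is a legal unit-cost rewrite:
#' a DCJ conserves extremities across at most two elements per side, an
#' insertion adds exactly the head and tail of one gene, a deletion removes
#' them.
#'
#' @param op An operation.
#' @return Logical.
#' @export
op_matches_schema <- function(op) {
  cl <- sort(unlist(op$consumed))
  pl <- sort(unlist(op$produced))
  sizes_c <- sort(lengths(op$consumed))
  sizes_p <- sort(lengths(op$produced))
  if (length(op$consumed) > 2L || length(op$produced) > 2L) return(FALSE)
  if (any(c(lengths(op$consumed), lengths(op$produced)) > 2L)) return(FALSE)
  if (op$kind == "DCJ") {
    if (!identical(cl, pl)) return(FALSE)
    nc <- length(op$consumed); np <- length(op$produced)
    if (nc == 2L && np == 2L) return(identical(sizes_c, sizes_p))
    if (nc == 2L && np == 1L) return(identical(sizes_c, c(1L, 1L)) && sizes_p == 2L)
    if (nc == 1L && np == 2L) return(sizes_c == 2L && identical(sizes_p, c(1L, 1L)))
    return(FALSE)
  }
  g <- op$gene
  pair <- sort(c(ext(g, "h"), ext(g, "t")))
  if (op$kind == "INS") {
    extra <- multiset_diff(pl, cl)
    return(length(cl) + 2L == length(pl) && identical(sort(extra), pair) &&
             length(multiset_diff(cl, pl)) == 0L)
  }
  if (op$kind == "DEL") {
    extra <- multiset_diff(cl, pl)
    return(length(pl) + 2L == length(cl) && identical(sort(extra), pair) &&
             length(multiset_diff(pl, cl)) == 0L)
  }
  FALSE
}

multiset_diff <- function(a, b) {
  out <- a
  for (x in b) {
    i <- match(x, out)
    if (!is.na(i)) out <- out[-i]
  }
  out
}

#' Replay and verify a scenario
#'
#' Folds [apply_operation()] over the scenario starting from `s1` and checks
#' that the final multiset equals `s2` and that the operation counts satisfy
#' the count law (`DEL = |T1|`, `INS = |T2|`).
#'
#' @param s1,s2 Adjacency sets of the source and target genomes.
#' @param sc A `dcj_scenario`.
#' @return List with `ok` and, on failure, `step` and `reason`.
#' @export
verify_scenario <- function(s1, sc, s2) {
  gp <- compute_ghosts(s1, s2)
  cur <- s1
  for (i in seq_along(sc$ops)) {
    op <- sc$ops[[i]]
    if (!op_matches_schema(op)) {
      return(list(ok = FALSE, step = i, reason = "operation matches no rewrite schema"))
    }
    cur <- tryCatch(apply_operation(cur, op), error = function(e) e)
    if (inherits(cur, "error")) {
      return(list(ok = FALSE, step = i, reason = conditionMessage(cur)))
    }
  }
  if (!aset_equal(cur, s2)) {
    return(list(ok = FALSE, step = length(sc$ops), reason = "final set differs from target"))
  }
  kinds <- vapply(sc$ops, `[[`, character(1), "kind")
  if (sum(kinds == "DEL") != length(gp$t1) || sum(kinds == "INS") != length(gp$t2)) {
    return(list(ok = FALSE, step = NA_integer_, reason = "operation counts violate the count law"))
  }
  list(ok = TRUE)
}
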