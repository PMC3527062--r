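# The adjacency graph: a bipartite multigraph whose left vertices are the
# elements of S1' united with the ghosts T2 and whose right vertices are
# S2' united with T1. Two elements are joined by one edge per shared
# extremity. Edges are never materialized: a decomposition IS a
# label-preserving bijection between left and right slot occurrences, and
# such a bijection induces exactly the vertex-disjoint alternating
# cycles/paths covering all vertices.

flatten_side <- function(elements) {
  ne <- length(elements)
  elem <- integer(0); pos <- integer(0); label <- character(0)
  for (i in seq_len(ne)) {
    sl <- elements[[i]]$slots
    elem <- c(elem, rep(i, length(sl)))
    pos <- c(pos, seq_along(sl))
    label <- c(label, sl)
  }
  sibling <- rep(NA_integer_, length(label))
  for (i in seq_len(ne)) {
    ids <- which(elem == i)
    if (length(ids) == 2L) sibling[ids] <- rev(ids)
  }
  list(elem = elem, pos = pos, label = label, sibling = sibling,
       origin = vapply(elements, `[[`, character(1), "origin"),
       is_tel = vapply(elements, is_telomere, logical(1)))
}

order_elements <- function(elements) {
  if (!length(elements)) return(elements)
  keys <- vapply(elements, element_key, character(1))
  origins <- vapply(elements, `[[`, character(1), "origin")
  elements[order(origins, keys, seq_along(elements))]
}

new_adjacency_graph <- function(left_elements, right_elements, capped) {
  left_elements <- order_elements(left_elements)
  right_elements <- order_elements(right_elements)
  L <- flatten_side(left_elements)
  R <- flatten_side(right_elements)
  lt <- sort(L$label)
  rt <- sort(R$label)
  if (!identical(lt, rt)) {
    stop("extremity label imbalance between the two sides of the adjacency graph",
         call. = FALSE)
  }
  structure(list(
    left = left_elements, right = right_elements,
    L = L, R = R,
    n = length(L$label) / 2,
    label_slots_right = split(seq_along(R$label), R$label),
    capped = capped
  ), class = "adjacency_graph")
}

#' Build the adjacency graph of a capped genome pair
#'
#' Left side: capped `S1` plus the `T2` ghosts; right side: capped `S2` plus
#' the `T1` ghosts. Elements on each side are deterministically ordered by
#' (origin, canonical label pair, input position).
#'
#' @param cp A [cap_telomeres()] result.
#' @param gp A [compute_ghosts()] result.
#' @return An `adjacency_graph` object; `$n` is half the number of
#'   extremities on one side.
#' @export
build_graph <- function(cp, gp) {
  new_adjacency_graph(c(cp$s1_capped$elements, gp$t2),
                      c(cp$s2_capped$elements, gp$t1),
                      capped = TRUE)
}

#' Build the uncapped adjacency graph of a genome pair
#'
#' As [build_graph()] but keeps telomeres as 1-slot vertices, so
#' decompositions contain paths as well as cycles. Used by the path-aware
#' oracle and the classic duplicate-free distance.
#'
#' @param s1,s2 Adjacency sets.
#' @param gp Ghosts from [compute_ghosts()] (computed if missing).
#' @return An `adjacency_graph` object.
#' @export
build_uncapped_graph <- function(s1, s2, gp = compute_ghosts(s1, s2)) {
  new_adjacency_graph(c(s1$elements, gp$t2),
                      c(s2$elements, gp$t1),
                      capped = FALSE)
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Adjacency graph:", length(x$left), "left /", length(x$right),
      "right elements, n =", x$n,
      if (x$capped) "(capped)" else "(uncapped)", "\n")
  invisible(x)
}

#' Construct a decomposition from a slot matching
#'
#' @param match Integer vector: `match[i]` is the right-slot index matched to
#'   left slot `i`.
#' @return A `dcj_decomposition` object.
#' @export
decomposition <- function(match) {
  inv <- integer(length(match))
  inv[match] <- seq_along(match)
  structure(list(match = as.integer(match), inv = inv),
            class = "dcj_decomposition")
}

#' Validate a decomposition against its graph
#'
#' Checks that the matching is total (a bijection of slot occurrences) and
#' label-preserving; alternation is implied by the slot encoding (the two
#' edges at any 2-slot element use its two distinct slots).
#'
#' @param graph An `adjacency_graph`.
#' @param d A [decomposition()].
#' @return List with `ok` (logical) and, on failure, `violation` and the
#'   offending `slots`.
#' @export
validate_decomposition <- function(graph, d) {
  ns <- length(graph$L$label)
  m <- d$match
  if (length(m) != ns || anyNA(m) || !setequal(m, seq_len(ns))) {
    bad <- if (length(m) != ns) integer(0) else which(is.na(m) | duplicated(m))
    return(list(ok = FALSE, violation = "totality", slots = bad))
  }
  mism <- which(graph$L$label != graph$R$label[m])
  if (length(mism)) {
    return(list(ok = FALSE, violation = "label", slots = mism[1L]))
  }
  list(ok = TRUE)
}

#' Components induced by a decomposition
#'
#' Walks the matched edges into vertex-disjoint alternating cycles and paths
#' covering all elements, and classifies each component.
#'
#' @param graph An `adjacency_graph`.
#' @param d A [decomposition()].
#' @return List of components; each has `kind` (`"cycle"`/`"path"`),
#'   `length` (edge count), `left_ids`/`right_ids`, `ghosts_left`/
#'   `ghosts_right`, `edges` (2-column matrix of left/right slot ids in
#'   traversal order) and `classification`.
#' @export
components_of <- function(graph, d) {
  chk <- validate_decomposition(graph, d)
  if (!chk$ok) {
    stop("invalid decomposition (", chk$violation, " violation)", call. = FALSE)
  }
  L <- graph$L; R <- graph$R
  ns <- length(L$label)
  # an edge is identified by its left slot; adjacent edges share an element
  visited <- rep(FALSE, ns)
  comps <- list()

  # walk from edge `e0`, first exiting via `side` ("left" or "right");
  # stops at a missing sibling (path end) or on returning to e0 (cycle)
  walk <- function(e0, side) {
    edges <- integer(0)
    e <- e0
    repeat {
      visited[e] <<- TRUE
      edges <- c(edges, e)
      nxt <- if (side == "right") {
        sib <- R$sibling[d$match[e]]
        if (is.na(sib)) NA_integer_ else d$inv[sib]
      } else {
        L$sibling[e]
      }
      if (is.na(nxt)) return(list(edges = edges, kind = "path"))
      if (nxt == e0) return(list(edges = edges, kind = "cycle"))
      e <- nxt
      side <- if (side == "right") "left" else "right"
    }
  }

  for (e in seq_len(ns)) {
    if (visited[e]) next
    lt <- is.na(L$sibling[e])
    rt <- is.na(R$sibling[d$match[e]])
    w <- if (lt) {
      walk(e, "right")       # left end is a telomere: go right-first
    } else if (rt) {
      walk(e, "left")        # right end is a telomere: go left-first
    } else {
      NULL
    }
    if (is.null(w)) next     # interior edge; cycles handled below
    comps[[length(comps) + 1L]] <- w
  }
  for (e in seq_len(ns)) {
    if (visited[e]) next
    comps[[length(comps) + 1L]] <- walk(e, "right")
  }

  lapply(comps, function(w) {
    finish_component(graph, list(edges = cbind(w$edges, d$match[w$edges]),
                                 kind = w$kind))
  })
}

finish_component <- function(graph, w) {
  L <- graph$L; R <- graph$R
  lids <- unique(L$elem[w$edges[, 1]])
  rids <- unique(R$elem[w$edges[, 2]])
  gl <- sum(L$origin[lids] == "ghost")
  gr <- sum(R$origin[rids] == "ghost")
  comp <- list(kind = w$kind, length = nrow(w$edges),
               left_ids = lids, right_ids = rids,
               ghosts_left = gl, ghosts_right = gr,
               edges = w$edges)
  comp$classification <- classify_component(comp)
  comp
}

#' Classify a component
#'
#' Cycles of length `l` are helpful when they contain at most `l/2 - 1`
#' ghost elements (an unhelpful cycle has exactly `l/2`, all on one side);
#' paths are classified by parity of their length.
#'
#' @param comp A component from [components_of()].
#' @return `"helpful"`, `"unhelpful"`, `"odd"` or `"even"`.
#' @export
classify_component <- function(comp) {
  if (comp$kind == "cycle") {
    ghosts <- comp$ghosts_left + comp$ghosts_right
    if (ghosts <= comp$length / 2 - 1) "helpful" else "unhelpful"
  } else {
    if (comp$length %% 2L == 1L) "odd" else "even"
  }
}

four_cycle_pairing <- function(L, R, li, lj, rk, rl, lslots, rslots) {
  # try to realize the alternating 4-cycle li-rk-lj-rl-li at slot level
  a <- lslots[[li]]; c <- lslots[[lj]]
  b <- rslots[[rk]]; d <- rslots[[rl]]
  for (ai in 1:2) for (bi in 1:2) for (ci in 1:2) for (di in 1:2) {
    a1 <- a[ai]; a2 <- a[3 - ai]
    b1 <- b[bi]; b2 <- b[3 - bi]
    c1 <- c[ci]; c2 <- c[3 - ci]
    d1 <- d[di]; d2 <- d[3 - di]
    if (L$label[a1] == R$label[b1] && L$label[c1] == R$label[b2] &&
        L$label[c2] == R$label[d1] && L$label[a2] == R$label[d2]) {
      return(cbind(c(a1, c1, c2, a2), c(b1, b2, d1, d2)))
    }
  }
  NULL
}

#' Enumerate helpful 4-cycles
#'
#' Collects all alternating cycles of length 4 (two left and two right
#' elements) containing at most one ghost element; candidates covering the
#' same four elements are deduplicated to one representative slot pairing.
#'
#' @param graph A capped `adjacency_graph`.
#' @return List of candidates with `left`, `right` (element id pairs),
#'   `ghosts`, and `pairing` (4x2 matrix of matched left/right slot ids).
#' @export
enumerate_helpful_4cycles <- function(graph) {
  L <- graph$L; R <- graph$R
  nl <- length(graph$left); nr <- length(graph$right)
  if (nl < 2L || nr < 2L) return(list())
  lslots <- split(seq_along(L$label), L$elem)
  rslots <- split(seq_along(R$label), R$elem)
  # right elements sharing at least one label with each left element
  rset <- vector("list", nl)
  for (i in seq_len(nl)) {
    labs <- L$label[lslots[[as.character(i)]]]
    ids <- unlist(graph$label_slots_right[labs], use.names = FALSE)
    rset[[i]] <- unique(R$elem[ids])
  }
  lslots <- lapply(seq_len(nl), function(i) lslots[[as.character(i)]])
  rslots <- lapply(seq_len(nr), function(i) rslots[[as.character(i)]])
  out <- list()
  for (i in seq_len(nl - 1L)) {
    for (j in (i + 1L):nl) {
      shared <- intersect(rset[[i]], rset[[j]])
      if (length(shared) < 2L) next
      ghost_ij <- (L$origin[i] == "ghost") + (L$origin[j] == "ghost")
      if (ghost_ij > 1L) next
      shared <- sort(shared)
      for (ki in seq_len(length(shared) - 1L)) {
        for (li2 in (ki + 1L):length(shared)) {
          rk <- shared[ki]; rl <- shared[li2]
          ghosts <- ghost_ij + (R$origin[rk] == "ghost") + (R$origin[rl] == "ghost")
          if (ghosts > 1L) next
          pairing <- four_cycle_pairing(L, R, i, j, rk, rl, lslots, rslots)
          if (is.null(pairing)) next
          out[[length(out) + 1L]] <- list(left = c(i, j), right = c(rk, rl),
                                          ghosts = ghosts, pairing = pairing)
        }
      }
    }
  }
  out
}
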