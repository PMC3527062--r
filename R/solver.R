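# Distance computation: helpful-4-cycle packing, decomposition completion,
# the brute-force optimal-decomposition oracle, telomere recovery, and the
# distance formula d = n - c - o/2.

candidate_cover <- function(cand, nl) {
  c(cand$left, cand$right + nl)
}

#' Pack element-disjoint helpful 4-cycles
#'
#' Maximum (or near-maximum) subset of candidate 4-cycles such that no two
#' share an element: the 4-set packing step of the approximation algorithm.
#'
#' @param candidates Candidates from [enumerate_helpful_4cycles()].
#' @param mode `"exact"` (branch-and-bound maximum packing) or
#'   `"greedy_local"` (greedy maximal packing improved by local search that
#'   swaps up to `swap_radius` selected cycles for more).
#' @param swap_radius Local-search radius (greedy mode).
#' @param seed RNG seed (tie-breaking is deterministic; the seed pins any
#'   residual randomness).
#' @param nl Number of left elements (namespaces the element universe).
#' @param exact_limit Refuse exact mode above this candidate count.
#' @return List with `selected` (indices into `candidates`) and `mode`.
#' @export
pack_cycles <- function(candidates, mode = c("exact", "greedy_local"),
                        swap_radius = 2L, seed = 0L, nl = NULL,
                        exact_limit = 512L) {
  mode <- match.arg(mode)
  nc <- length(candidates)
  if (!nc) return(list(selected = integer(0), mode = mode))
  if (is.null(nl)) nl <- max(unlist(lapply(candidates, `[[`, "left"))) + 0L
  covers <- lapply(candidates, candidate_cover, nl = nl)
  if (mode == "exact") {
    if (nc > exact_limit) {
      stop("exact packing refused for ", nc, " candidates (limit ", exact_limit,
           "); use mode = \"greedy_local\"", call. = FALSE)
    }
    return(list(selected = pack_exact(covers), mode = mode))
  }
  set.seed(seed)
  list(selected = pack_greedy_local(covers, swap_radius), mode = mode)
}

pack_exact <- function(covers) {
  nc <- length(covers)
  best <- integer(0)
  used <- character(0)
  # order by ascending conflict degree helps the bound
  conf <- vapply(seq_len(nc), function(i) {
    sum(vapply(covers, function(cv) any(cv %in% covers[[i]]), logical(1))) - 1L
  }, integer(1))
  ord <- order(conf, seq_len(nc))
  covers <- covers[ord]
  used_elems <- integer(0)
  chosen <- integer(0)
  recurse <- function(i) {
    if (length(chosen) + (nc - i + 1L) <= length(best)) return(invisible())
    if (i > nc) {
      if (length(chosen) > length(best)) best <<- chosen
      return(invisible())
    }
    cv <- covers[[i]]
    if (!any(cv %in% used_elems)) {
      used_elems <<- c(used_elems, cv)
      chosen <<- c(chosen, i)
      recurse(i + 1L)
      chosen <<- chosen[-length(chosen)]
      used_elems <<- used_elems[seq_len(length(used_elems) - 4L)]
    }
    recurse(i + 1L)
    invisible()
  }
  recurse(1L)
  sort(ord[best])
}

pack_greedy_local <- function(covers, swap_radius) {
  nc <- length(covers)
  selected <- integer(0)
  used <- integer(0)
  for (i in seq_len(nc)) {
    if (!any(covers[[i]] %in% used)) {
      selected <- c(selected, i)
      used <- c(used, covers[[i]])
    }
  }
  # Hurkens-Schrijver style (r, r+1) swaps
  repeat {
    improved <- FALSE
    for (r in seq_len(min(swap_radius, length(selected)))) {
      subs <- utils::combn(selected, r, simplify = FALSE)
      for (drop_set in subs) {
        keep <- setdiff(selected, drop_set)
        used_keep <- unlist(covers[keep], use.names = FALSE)
        free_cand <- setdiff(seq_len(nc), keep)
        free_cand <- free_cand[vapply(free_cand, function(i) {
          !any(covers[[i]] %in% used_keep)
        }, logical(1))]
        add <- find_disjoint(covers, free_cand, r + 1L)
        if (!is.null(add)) {
          selected <- sort(c(keep, add))
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  selected
}

find_disjoint <- function(covers, pool, want) {
  # DFS for `want` pairwise-disjoint candidates within `pool`
  rec <- function(pool, used, got) {
    if (length(got) == want) return(got)
    if (length(pool) < want - length(got)) return(NULL)
    i <- pool[1L]
    rest <- pool[-1L]
    if (!any(covers[[i]] %in% used)) {
      res <- rec(rest, c(used, covers[[i]]), c(got, i))
      if (!is.null(res)) return(res)
    }
    rec(rest, used, got)
  }
  rec(pool, integer(0), integer(0))
}

# --- decomposition completion -------------------------------------------

# commit all identical ghost-free left/right element pairs as 2-cycles;
# rewiring any decomposition through such a pair never loses helpful cycles
precommit_identical <- function(graph, match) {
  L <- graph$L; R <- graph$R
  lfree <- which(is.na(match) & !L$is_tel[L$elem] &
                   L$origin[L$elem] != "ghost")
  lelems <- unique(L$elem[lfree])
  rslot_used <- rep(FALSE, length(R$label))
  rslot_used[match[!is.na(match)]] <- TRUE
  lkeys <- vapply(graph$left, element_key, character(1))
  rkeys <- vapply(graph$right, element_key, character(1))
  rorigin <- R$origin
  for (le in lelems) {
    ls <- which(L$elem == le)
    if (any(!is.na(match[ls]))) next
    # find a fully free, ghost-free right element with the same key
    cand <- which(rkeys == lkeys[le] & rorigin != "ghost")
    ok <- NA_integer_
    for (re in cand) {
      rs <- which(R$elem == re)
      if (!any(rslot_used[rs])) { ok <- re; break }
    }
    if (is.na(ok)) next
    rs <- which(R$elem == ok)
    # pair label-consistently
    for (s1 in ls) {
      hit <- rs[!rslot_used[rs] & R$label[rs] == L$label[s1]][1L]
      match[s1] <- hit
      rslot_used[hit] <- TRUE
    }
  }
  match
}

#' Complete a partial decomposition
#'
#' Fixes the slot pairings of the packed 4-cycles and matches all remaining
#' slots label-consistently into cycles, greedily closing the shortest
#' available cycle from the lowest-indexed open slot (which opportunistically
#' pairs identical elements into helpful 2-cycles).
#'
#' @param graph A capped `adjacency_graph`.
#' @param packing A [pack_cycles()] result.
#' @param candidates The candidate list the packing indexes into.
#' @param partial Optional pre-seeded match vector (internal use).
#' @return A valid [decomposition()].
#' @export
complete_decomposition <- function(graph, packing, candidates = list(),
                                   partial = NULL) {
  ns <- length(graph$L$label)
  match <- partial %||% rep(NA_integer_, ns)
  for (i in packing$selected) {
    p <- candidates[[i]]$pairing
    match[p[, 1]] <- p[, 2]
  }
  match <- precommit_identical(graph, match)
  match <- complete_greedy(graph, match)
  decomposition(match)
}

complete_greedy <- function(graph, match) {
  L <- graph$L; R <- graph$R
  ns <- length(L$label)
  rfree <- rep(TRUE, length(R$label))
  rfree[match[!is.na(match)]] <- FALSE
  repeat {
    open <- which(is.na(match))
    if (!length(open)) break
    ls0 <- open[1L]
    res <- shortest_closure(graph, match, rfree, ls0)
    if (is.null(res)) res <- greedy_walk_closure(graph, match, rfree, ls0)
    match[res$lslots] <- res$rslots
    rfree[res$rslots] <- FALSE
  }
  match
}

# BFS for the shortest alternating cycle through ls0's element using free
# slots; tracks used slots along each candidate path so the result is valid
shortest_closure <- function(graph, match, rfree, ls0) {
  L <- graph$L; R <- graph$R
  start_lab <- L$label[ls0]
  p0 <- L$sibling[ls0]
  # state: pending slot to be matched; parent pointers rebuild the matches
  q_side <- "L"; queue <- list(list(slot = p0, side = "L", parent = 0L, via = NA_integer_))
  seen <- new.env(hash = TRUE)
  assign(paste0("L", p0), TRUE, envir = seen)
  head <- 1L
  path_slots <- function(node) {
    out <- integer(0)
    while (node != 0L) {
      st <- queue[[node]]
      out <- c(out, st$slot, st$via)
      node <- st$parent
    }
    out[!is.na(out)]
  }
  while (head <= length(queue)) {
    st <- queue[[head]]
    usedp <- path_slots(head)
    if (st$side == "L") {
      cands <- which(rfree & R$label == L$label[st$slot])
      for (r in cands) {
        if (r %in% usedp) next
        sib <- R$sibling[r]
        if (sib %in% usedp) next
        key <- paste0("R", sib)
        if (exists(key, envir = seen, inherits = FALSE)) next
        assign(key, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- list(slot = sib, side = "R",
                                            parent = head, via = r)
      }
    } else {
      # pending right slot: match with a free left slot; ls0 closes the cycle
      if (R$label[st$slot] == start_lab) {
        # reconstruct the matched pairs along the chain plus the closing pair
        lsl <- ls0; rsl <- st$slot
        node <- head
        while (node != 0L) {
          s <- queue[[node]]
          if (s$side == "R") {
            # parent L-state's pending slot was matched to s$via
            lsl <- c(lsl, queue[[s$parent]]$slot)
            rsl <- c(rsl, s$via)
          } else if (s$parent != 0L) {
            # non-initial L-state: s$via was matched to parent R-state's slot
            lsl <- c(lsl, s$via)
            rsl <- c(rsl, queue[[s$parent]]$slot)
          }
          node <- s$parent
        }
        return(list(lslots = lsl, rslots = rsl))
      }
      cands <- which(is.na(match) & L$label == R$label[st$slot])
      cands <- setdiff(cands, ls0)
      for (l in cands) {
        if (l %in% usedp) next
        sib <- L$sibling[l]
        if (sib %in% usedp) next
        key <- paste0("L", sib)
        if (exists(key, envir = seen, inherits = FALSE)) next
        assign(key, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- list(slot = sib, side = "L",
                                            parent = head, via = l)
      }
    }
    head <- head + 1L
  }
  NULL
}

greedy_walk_closure <- function(graph, match, rfree, ls0) {
  L <- graph$L; R <- graph$R
  lsl <- integer(0); rsl <- integer(0)
  lused <- c(ls0)
  pend <- L$sibling[ls0]; side <- "L"
  repeat {
    if (side == "L") {
      cands <- which(rfree & R$label == L$label[pend] & !(seq_along(rfree) %in% rsl))
      stopifnot(length(cands) > 0L)
      r <- cands[1L]
      lsl <- c(lsl, pend); rsl <- c(rsl, r)
      pend <- R$sibling[r]; side <- "R"
    } else {
      lab <- R$label[pend]
      if (lab == L$label[ls0]) {
        lsl <- c(lsl, ls0); rsl <- c(rsl, pend)
        return(list(lslots = lsl, rslots = rsl))
      }
      cands <- which(is.na(match) & L$label == lab &
                       !(seq_along(match) %in% c(lsl, ls0)))
      stopifnot(length(cands) > 0L)
      l <- cands[1L]
      lsl <- c(lsl, l); rsl <- c(rsl, pend)
      pend <- L$sibling[l]; side <- "L"
    }
  }
}

# --- exact oracle --------------------------------------------------------

#' Optimal decomposition by exhaustive branch-and-bound
#'
#' Enumerates label-preserving slot bijections component by component,
#' maximizing the number of helpful cycles plus half the number of odd
#' paths, with symmetry reduction over identical elements and an upper-bound
#' prune. The graph is first split into its connected parts (element sets
#' linked by shared extremity labels), which are solved independently. On
#' capped graphs all components are cycles.
#'
#' @param graph An `adjacency_graph` (capped or uncapped).
#' @param max_side Refuse instances with more elements per side than this.
#' @return List with `decomposition`, `c`, `o`, `value` (`c + o/2`) and
#'   `distance` (`n - c - o/2`).
#' @export
exact_best_decomposition <- function(graph, max_side = 12L) {
  nl <- length(graph$left); nr <- length(graph$right)
  if (max(nl, nr) > max_side) {
    stop("instance above oracle size cap (", max(nl, nr), " > ", max_side,
         " elements per side)", call. = FALSE)
  }
  parts <- connected_parts(graph)
  if (length(parts) > 1L) {
    match <- rep(NA_integer_, length(graph$L$label))
    for (part in parts) {
      sub <- new_adjacency_graph(graph$left[part$l], graph$right[part$r],
                                 graph$capped)
      res <- oracle_search(sub)
      # map subgraph slot indices back to the parent graph
      lmap <- slot_map(graph$L, sub$L, part$l)
      rmap <- slot_map(graph$R, sub$R, part$r)
      match[lmap] <- rmap[res$match]
    }
    d <- decomposition(match)
  } else {
    d <- decomposition(oracle_search(graph)$match)
  }
  comps <- components_of(graph, d)
  cls <- vapply(comps, `[[`, character(1), "classification")
  cc <- sum(cls == "helpful")
  oo <- sum(cls == "odd")
  list(decomposition = d, c = cc, o = oo, value = cc + oo / 2,
       distance = graph$n - cc - oo / 2)
}

# elements linked (transitively) by shared extremity labels
connected_parts <- function(graph) {
  nl <- length(graph$left); nr <- length(graph$right)
  parent <- seq_len(nl + nr)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  for (lab in unique(graph$L$label)) {
    ids <- c(graph$L$elem[graph$L$label == lab],
             graph$R$elem[graph$R$label == lab] + nl)
    for (i in seq_along(ids)[-1L]) union2(ids[1L], ids[i])
  }
  roots <- vapply(seq_len(nl + nr), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    ids <- which(roots == r)
    out[[length(out) + 1L]] <- list(l = ids[ids <= nl], r = ids[ids > nl] - nl)
  }
  out
}

# parent slot ids of a subgraph side, in subgraph slot order
slot_map <- function(parentF, subF, part_ids) {
  # subgraph element j corresponds to parent element part_ids_sorted[j] as
  # ordered by new_adjacency_graph; recover by matching keys/origins/pos
  # through the deterministic ordering applied to the same element objects
  ord <- order_elements_idx(parentF, part_ids)
  vapply(seq_along(subF$label), function(s) {
    pe <- ord[subF$elem[s]]
    which(parentF$elem == pe)[subF$pos[s]]
  }, integer(1))
}

order_elements_idx <- function(F, ids) {
  keys <- vapply(ids, function(i) {
    paste(sort(F$label[F$elem == i]), collapse = "~")
  }, character(1))
  origins <- F$origin[ids]
  ids[order(origins, keys, seq_along(ids))]
}

oracle_search <- function(graph) {
  L <- graph$L; R <- graph$R
  nl <- length(graph$left); nr <- length(graph$right)
  ns <- length(L$label)
  lkeys <- vapply(graph$left, element_key, character(1))
  rkeys <- vapply(graph$right, element_key, character(1))
  lghost <- L$origin == "ghost"
  rghost <- R$origin == "ghost"

  match <- rep(NA_integer_, ns)
  rfree <- rep(TRUE, length(R$label))
  # element fully-free trackers for the bound
  lfree_el <- rep(TRUE, nl)
  rfree_el <- rep(TRUE, nr)

  best <- list(value = -1, match = NULL, c = 0L, o = 0L)

  ub_rest <- function() {
    lf <- which(lfree_el); rf <- which(rfree_el)
    l2 <- lf[!L$is_tel[lf] & !lghost[lf]]
    r2 <- rf[!R$is_tel[rf] & !rghost[rf]]
    cyc <- min(length(l2), length(r2))
    if (graph$capped) return(cyc)
    lt <- sum(L$is_tel[lf]); rt <- sum(R$is_tel[rf])
    cyc + min(lt, rt) / 2
  }

  # candidate right slots for a pending left slot, with symmetry reduction
  cand_r <- function(lab) {
    ids <- graph$label_slots_right[[lab]]
    ids <- ids[rfree[ids]]
    if (length(ids) <= 1L) return(ids)
    sig <- ifelse(rfree_el[R$elem[ids]],
                  paste0("f:", rkeys[R$elem[ids]], ":", R$origin[R$elem[ids]]),
                  paste0("p:", ids))
    ids[!duplicated(sig)]
  }
  label_slots_left <- split(seq_along(L$label), L$label)
  cand_l <- function(lab) {
    ids <- label_slots_left[[lab]]
    ids <- ids[is.na(match[ids])]
    if (length(ids) <= 1L) return(ids)
    sig <- ifelse(lfree_el[L$elem[ids]],
                  paste0("f:", lkeys[L$elem[ids]], ":", L$origin[L$elem[ids]]),
                  paste0("p:", ids))
    ids[!duplicated(sig)]
  }

  do_match <- function(l, r) {
    match[l] <<- r
    rfree[r] <<- FALSE
    lfree_el[L$elem[l]] <<- FALSE
    rfree_el[R$elem[r]] <<- FALSE
  }
  undo_match <- function(l, r) {
    match[l] <<- NA_integer_
    rfree[r] <<- TRUE
    if (all(is.na(match[which(L$elem == L$elem[l])]))) lfree_el[L$elem[l]] <<- TRUE
    if (all(rfree[which(R$elem == R$elem[r])])) rfree_el[R$elem[r]] <<- TRUE
  }

  # value accumulated over completed components
  search <- function(cur) {
    if (cur + ub_rest() <= best$value) return(invisible())
    open_tel_l <- which(is.na(match) & is.na(L$sibling))
    if (length(open_tel_l)) {
      start_path(open_tel_l[1L], cur)
      return(invisible())
    }
    open_tel_r <- which(rfree & is.na(R$sibling))
    if (length(open_tel_r)) {
      start_path_right(open_tel_r[1L], cur)
      return(invisible())
    }
    open <- which(is.na(match))
    if (!length(open)) {
      if (cur > best$value) {
        best <<- list(value = cur, match = match, c = NA, o = NA)
      }
      return(invisible())
    }
    start_cycle(open[1L], cur)
    invisible()
  }

  # build a path starting at left telomere slot lt
  start_path <- function(lt, cur) {
    extend_path <- function(pend, side, len, ghosts, cur) {
      if (side == "L") {
        for (r in cand_r(L$label[pend])) {
          do_match(pend, r)
          if (is.na(R$sibling[r])) {
            # path ends at a right telomere; length len+1
            v <- if ((len + 1L) %% 2L == 1L) 0.5 else 0
            search(cur + v)
          } else {
            extend_path(R$sibling[r], "R", len + 1L, ghosts, cur)
          }
          undo_match(pend, r)
        }
      } else {
        for (l in cand_l(R$label[pend])) {
          do_match(l, pend)
          if (is.na(L$sibling[l])) {
            v <- if ((len + 1L) %% 2L == 1L) 0.5 else 0
            search(cur + v)
          } else {
            extend_path(L$sibling[l], "L", len + 1L, ghosts, cur)
          }
          undo_match(l, pend)
        }
      }
      invisible()
    }
    extend_path(lt, "L", 0L, 0L, cur)
    invisible()
  }

  start_path_right <- function(rt, cur) {
    extend <- function(pend_r, len, cur) {
      for (l in cand_l(R$label[pend_r])) {
        do_match(l, pend_r)
        if (is.na(L$sibling[l])) {
          v <- if ((len + 1L) %% 2L == 1L) 0.5 else 0
          search(cur + v)
        } else {
          # continue: sibling of l pends on the left
          pend_l <- L$sibling[l]
          for (r in cand_r(L$label[pend_l])) {
            do_match(pend_l, r)
            if (is.na(R$sibling[r])) {
              v <- if ((len + 2L) %% 2L == 1L) 0.5 else 0
              search(cur + v)
            } else {
              extend(R$sibling[r], len + 2L, cur)
            }
            undo_match(pend_l, r)
          }
        }
        undo_match(l, pend_r)
      }
      invisible()
    }
    extend(rt, 0L, cur)
    invisible()
  }

  # build a cycle anchored at left slot ls0 (its match closes the cycle)
  start_cycle <- function(ls0, cur) {
    anchor_lab <- L$label[ls0]
    extend <- function(pend, side, len, ghosts, elems_l, elems_r, cur) {
      if (side == "L") {
        for (r in cand_r(L$label[pend])) {
          do_match(pend, r)
          extend(R$sibling[r], "R", len + 1L, ghosts + rghost[R$elem[r]],
                 elems_l, elems_r + 1L, cur)
          undo_match(pend, r)
        }
      } else {
        lab <- R$label[pend]
        # closing option
        if (lab == anchor_lab) {
          do_match(ls0, pend)
          helpful <- (ghosts <= (len + 1L) / 2 - 1)
          search(cur + (if (helpful) 1 else 0))
          undo_match(ls0, pend)
        }
        for (l in cand_l(lab)) {
          if (l == ls0) next
          do_match(l, pend)
          extend(L$sibling[l], "L", len + 1L, ghosts + lghost[L$elem[l]],
                 elems_l + 1L, elems_r, cur)
          undo_match(l, pend)
        }
      }
      invisible()
    }
    g0 <- as.integer(lghost[L$elem[ls0]])
    extend(L$sibling[ls0], "L", 1L, g0, 1L, 0L, cur)
    invisible()
  }

  search(0)
  if (is.null(best$match)) stop("oracle search failed", call. = FALSE)
  list(match = best$match, value = best$value)
}

# --- recovery and distance ----------------------------------------------

node_from_element <- function(el, side) {
  list(side = side, labels = el$slots, ghost = el$origin == "ghost",
       tel = is_telomere(el))
}

# turn a capped/uncapped component into a standalone node chain
component_chain <- function(graph, comp) {
  E <- comp$edges
  m <- nrow(E)
  lab <- graph$L$label[E[, 1]]
  if (m == 1L) {
    nodes <- list(node_from_element(graph$left[[graph$L$elem[E[1, 1]]]], "L"),
                  node_from_element(graph$right[[graph$R$elem[E[1, 2]]]], "R"))
  } else {
    share_right1 <- graph$R$elem[E[1, 2]] == graph$R$elem[E[2, 2]]
    first_side <- if (share_right1) "L" else "R"
    n1 <- if (first_side == "L") {
      node_from_element(graph$left[[graph$L$elem[E[1, 1]]]], "L")
    } else {
      node_from_element(graph$right[[graph$R$elem[E[1, 2]]]], "R")
    }
    nodes <- list(n1)
    side <- first_side
    for (i in seq_len(m)) {
      side <- if (side == "L") "R" else "L"
      el <- if (side == "L") {
        node_from_element(graph$left[[graph$L$elem[E[i, 1]]]], "L")
      } else {
        node_from_element(graph$right[[graph$R$elem[E[i, 2]]]], "R")
      }
      nodes[[length(nodes) + 1L]] <- el
    }
    if (comp$kind == "cycle") nodes <- nodes[seq_len(m)]
  }
  chain <- list(kind = comp$kind, nodes = nodes, edge_labels = lab)
  chain$classification <- chain_classification(chain)
  chain
}

chain_classification <- function(chain) {
  len <- length(chain$edge_labels)
  if (chain$kind == "cycle") {
    ghosts <- sum(vapply(chain$nodes, `[[`, logical(1), "ghost"))
    if (ghosts <= len / 2 - 1) "helpful" else "unhelpful"
  } else {
    if (len %% 2L == 1L) "odd" else "even"
  }
}

#' Recover telomeres from a capped decomposition
#'
#' Removes all matched null-extremity edges, drops the tau-tau padding
#' elements and restores x-tau caps to telomeres, splitting each affected
#' cycle into paths (one per removed edge, tau-tau elements vanishing).
#'
#' @param graph The capped `adjacency_graph` the decomposition was built on.
#' @param d A [decomposition()] of `graph`.
#' @return List of recovered components ("chains": `kind`, `nodes`,
#'   `edge_labels`, `classification`) on the uncapped instance.
#' @export
recover_uncapped <- function(graph, d) {
  comps <- components_of(graph, d)
  out <- list()
  for (comp in comps) {
    chain <- component_chain(graph, comp)
    out <- c(out, decap_chain(chain))
  }
  out
}

strip_tau_node <- function(nd) {
  keep <- !is_tau(nd$labels)
  nd$labels <- nd$labels[keep]
  nd$tel <- length(nd$labels) == 1L
  nd
}

decap_chain <- function(chain) {
  tau_edges <- which(is_tau(chain$edge_labels))
  if (!length(tau_edges)) {
    chain$classification <- chain_classification(chain)
    return(list(chain))
  }
  m <- length(chain$edge_labels)
  stopifnot(chain$kind == "cycle")  # capped decompositions are cycles only
  # cut the cycle at every tau edge; each maximal run of non-tau edges is a
  # path whose end nodes lose their tau slot
  segs <- list()
  edge_nodes <- function(i) c(i, if (i == m) 1L else i + 1L)
  keep <- setdiff(seq_len(m), tau_edges)
  if (length(keep)) {
    # group consecutive (circularly) kept edges
    runs <- split_runs_circular(keep, m)
    for (run in runs) {
      node_ids <- c(run, if (run[length(run)] == m) 1L else run[length(run)] + 1L)
      nodes <- chain$nodes[node_ids]
      nodes[[1L]] <- strip_tau_node(nodes[[1L]])
      nodes[[length(nodes)]] <- strip_tau_node(nodes[[length(nodes)]])
      seg <- list(kind = "path", nodes = nodes,
                  edge_labels = chain$edge_labels[run])
      seg$classification <- chain_classification(seg)
      segs[[length(segs) + 1L]] <- seg
    }
  }
  segs
}

# split sorted positions into runs that are consecutive modulo m
split_runs_circular <- function(keep, m) {
  all_pos <- rep(FALSE, m)
  all_pos[keep] <- TRUE
  runs <- list()
  visited <- rep(FALSE, m)
  for (s in keep) {
    if (visited[s]) next
    prev <- if (s == 1L) m else s - 1L
    if (all_pos[prev]) next  # not a run start
    run <- integer(0)
    i <- s
    while (all_pos[i] && !visited[i]) {
      visited[i] <- TRUE
      run <- c(run, i)
      i <- if (i == m) 1L else i + 1L
    }
    runs[[length(runs) + 1L]] <- run
  }
  if (!length(runs) && length(keep)) runs <- list(keep)  # all edges kept
  runs
}

#' Distance from classified components
#'
#' Evaluates `d = n - c - o/2` where `c` counts helpful cycles and `o`
#' odd-length paths.
#'
#' @param n Half the number of extremities on one side of the graph the
#'   components came from.
#' @param comps Components (from [components_of()] or [recover_uncapped()]).
#' @return List with `distance`, `n`, `c`, `o`.
#' @export
distance_from_components <- function(n, comps) {
  cls <- vapply(comps, `[[`, character(1), "classification")
  cc <- sum(cls == "helpful")
  oo <- sum(cls == "odd")
  d <- n - cc - oo / 2
  if (d != round(d)) stop("non-integer distance: component bookkeeping bug",
                          call. = FALSE)
  list(distance = as.integer(round(d)), n = n, c = cc, o = oo)
}

#' Edit distance between two genomes
#'
#' Full pipeline: ghost adjacencies for content differences, null-extremity
#' capping, adjacency graph, helpful 4-cycle enumeration and packing,
#' greedy completion, helpful-cycle count of the completed decomposition,
#' and telomere recovery for the scenario-ready components. `method =
#' "exact"` replaces packing + completion by the brute-force optimal
#' decomposition (small instances only).
#'
#' @param a,b Genomes ([genome()]) or adjacency sets.
#' @param method `"approx"` (default) or `"exact"`.
#' @param packing `"auto"` (exact branch-and-bound up to `auto_limit`
#'   candidates, greedy + local search above), `"exact"`, or
#'   `"greedy_local"`.
#' @param swap_radius Local-search radius for greedy packing.
#' @param seed Seed for any randomized tie-breaking.
#' @param max_side Oracle size cap (exact method).
#' @param auto_limit Candidate-count threshold for `packing = "auto"`.
#' @return A `dcj_distance_report`: `distance`, `n` (post-capping),
#'   `n_uncapped`, `c`, `o`, `t1_size`, `t2_size`, `k1`, `k2`, `method`,
#'   plus the witnessing graph, decomposition and recovered components.
#' @export
#' @examples
#' gs <- parse_genomes(c(">A", "a b )", ">B", "a -b )"))
#' edit_distance(gs$A, gs$B)$distance
edit_distance <- function(a, b, method = c("approx", "exact"),
                          packing = c("auto", "exact", "greedy_local"),
                          swap_radius = 2L, seed = 0L, max_side = 12L,
                          auto_limit = 24L) {
  method <- match.arg(method)
  packing <- match.arg(packing)
  s1 <- if (inherits(a, "adjacency_set")) a else genome_to_adjacency_set(a)
  s2 <- if (inherits(b, "adjacency_set")) b else genome_to_adjacency_set(b)
  gp <- compute_ghosts(s1, s2)
  cp <- cap_telomeres(s1, s2)
  n_uncapped <- (length(aset_extremities(s1)) + length(gp$t2) * 2) / 2

  if (method == "exact") {
    # the oracle runs on the uncapped graph (paths enumerated directly):
    # telomere capping leaves the distance unchanged but multiplies the
    # search space through the interchangeable null extremities
    ugraph <- build_uncapped_graph(s1, s2, gp)
    oracle <- exact_best_decomposition(ugraph, max_side = max_side)
    comps <- components_of(ugraph, oracle$decomposition)
    recovered <- lapply(comps, function(cm) component_chain(ugraph, cm))
    n_capped <- n_uncapped + max(cp$k1, cp$k2)
    return(structure(list(
      distance = as.integer(oracle$distance), n = n_capped,
      n_uncapped = n_uncapped,
      c = oracle$c, o = oracle$o,
      t1_size = length(gp$t1), t2_size = length(gp$t2),
      k1 = cp$k1, k2 = cp$k2,
      method = method, packing_mode = NA_character_,
      swap_radius = swap_radius, seed = seed,
      s1 = s1, s2 = s2, ghosts = gp, graph = ugraph,
      decomposition = oracle$decomposition, components = comps,
      recovered = recovered
    ), class = "dcj_distance_report"))
  }

  graph <- build_graph(cp, gp)
  cands <- enumerate_helpful_4cycles(graph)
  # identical ghost-free pairs are committed first; candidates touching
  # them are discarded before packing
  pre <- precommit_identical(graph, rep(NA_integer_, length(graph$L$label)))
  taken_l <- unique(graph$L$elem[!is.na(pre)])
  taken_r <- unique(graph$R$elem[pre[!is.na(pre)]])
  cands <- Filter(function(cd) {
    !any(cd$left %in% taken_l) && !any(cd$right %in% taken_r)
  }, cands)
  packing_mode <- if (packing == "auto") {
    if (length(cands) <= auto_limit) "exact" else "greedy_local"
  } else packing
  pk <- pack_cycles(cands, mode = packing_mode, swap_radius = swap_radius,
                    seed = seed, nl = length(graph$left))
  d <- complete_decomposition(graph, pk, cands, partial = pre)

  comps <- components_of(graph, d)
  recovered <- recover_uncapped(graph, d)
  # the achievable operation count is determined by the recovered (uncapped)
  # components; it is never worse than the capped helpful-cycle count
  dist <- distance_from_components(n_uncapped, recovered)
  structure(list(
    distance = dist$distance, n = graph$n, n_uncapped = n_uncapped,
    c = dist$c, o = dist$o,
    t1_size = length(gp$t1), t2_size = length(gp$t2),
    k1 = cp$k1, k2 = cp$k2,
    method = method, packing_mode = if (method == "approx") packing_mode else NA_character_,
    swap_radius = swap_radius, seed = seed,
    s1 = s1, s2 = s2, ghosts = gp, graph = graph,
    decomposition = d, components = comps, recovered = recovered
  ), class = "dcj_distance_report")
}

#' @export
print.dcj_distance_report <- function(x, ...) {
  cat("DCJ-indel edit distance:", x$distance,
      sprintf("(method %s, n = %s, c = %s, o = %s, |T1| = %s, |T2| = %s)\n",
              x$method, x$n_uncapped, x$c, x$o, x$t1_size, x$t2_size))
  invisible(x)
}

#' Classic DCJ distance for duplicate-free equal-content genomes
#'
#' Independent direct computation used for cross-checking: builds the
#' degree-<=2 adjacency graph by label lookup (no ghosts, no capping, no
#' decomposition search) and walks its cycles and paths directly;
#' `d = n - c - o/2`.
#'
#' @param a,b Genomes or adjacency sets with equal content and no duplicate
#'   genes.
#' @return Integer distance.
#' @export
classic_dcj_distance <- function(a, b) {
  s1 <- if (inherits(a, "adjacency_set")) a else genome_to_adjacency_set(a)
  s2 <- if (inherits(b, "adjacency_set")) b else genome_to_adjacency_set(b)
  loc <- function(s) {
    # label -> c(element, slot) ; duplicates forbidden
    tab <- list()
    for (i in seq_along(s$elements)) {
      for (x in s$elements[[i]]$slots) {
        if (!is.null(tab[[x]])) stop("duplicate gene content", call. = FALSE)
        tab[[x]] <- i
      }
    }
    tab
  }
  t1 <- loc(s1); t2 <- loc(s2)
  if (!setequal(names(t1), names(t2))) stop("unequal gene content", call. = FALSE)
  n <- length(t1) / 2
  e1 <- s1$elements; e2 <- s2$elements
  # every extremity label is one graph edge; two labels are adjacent when
  # they share an element on either side, so components are label sets
  seen <- new.env(hash = TRUE)
  c_count <- 0L; o_count <- 0L
  for (start in names(t1)) {
    if (exists(start, envir = seen, inherits = FALSE)) next
    frontier <- start
    comp <- character(0)
    has_tel <- FALSE
    while (length(frontier)) {
      lab <- frontier[1L]
      frontier <- frontier[-1L]
      if (exists(lab, envir = seen, inherits = FALSE)) next
      assign(lab, TRUE, envir = seen)
      comp <- c(comp, lab)
      for (el in list(e1[[t1[[lab]]]], e2[[t2[[lab]]]])) {
        if (is_telomere(el)) {
          has_tel <- TRUE
        } else {
          other <- el$slots[-match(lab, el$slots)]
          if (!exists(other, envir = seen, inherits = FALSE)) {
            frontier <- c(frontier, other)
          }
        }
      }
    }
    if (has_tel) {
      if (length(comp) %% 2L == 1L) o_count <- o_count + 1L
    } else {
      c_count <- c_count + 1L
    }
  }
  as.integer(n - c_count - o_count / 2)
}
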