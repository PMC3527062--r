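# Random genomes with duplicate genes, and randomized operation histories
# with known length (hence a known upper bound on the true distance).

#' Simulation configuration
#'
#' @param families Number of gene families.
#' @param copy_rate Expected number of extra copies per family (Poisson).
#' @param chromosomes Number of chromosomes (reduced if there are fewer
#'   genes than chromosomes).
#' @param circular_fraction Probability that a chromosome is circular.
#' @param ops Length of the random operation history.
#' @param weights Named sampling probabilities for `DCJ`, `INS`, `DEL`
#'   (must sum to 1).
#' @param seed RNG seed; all simulator draws are deterministic given it.
#' @param max_copies Cap on the copy number drawn per family.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(families = 5L, copy_rate = 0.3,
                              chromosomes = 2L, circular_fraction = 0.5,
                              ops = 3L,
                              weights = c(DCJ = 0.6, INS = 0.2, DEL = 0.2),
                              seed = 0L, max_copies = Inf) {
  stopifnot(families >= 1L, copy_rate >= 0, chromosomes >= 1L,
            circular_fraction >= 0, circular_fraction <= 1, ops >= 0L,
            abs(sum(weights) - 1) < 1e-9,
            all(c("DCJ", "INS", "DEL") %in% names(weights)))
  structure(list(families = as.integer(families), copy_rate = copy_rate,
                 chromosomes = as.integer(chromosomes),
                 circular_fraction = circular_fraction, ops = as.integer(ops),
                 weights = weights, seed = as.integer(seed),
                 max_copies = max_copies),
            class = "simulation_config")
}

#' Random genome with duplicate genes
#'
#' Draws per-family copy numbers (1 plus Poisson(`copy_rate`), capped at
#' `max_copies`), shuffles all gene copies with random orientations and
#' splits them into chromosomes with random topologies.
#'
#' @param cfg A [simulation_config()].
#' @param name Genome name.
#' @return A [genome()]; deterministic given `cfg$seed`.
#' @export
random_genome <- function(cfg, name = "sim") {
  set.seed(cfg$seed)
  fams <- paste0("g", seq_len(cfg$families))
  copies <- 1L + pmin(stats::rpois(cfg$families, cfg$copy_rate),
                      cfg$max_copies - 1L)
  pool <- rep(fams, times = copies)
  pool <- sample(pool)
  signs <- sample(c(-1L, 1L), length(pool), replace = TRUE)
  k <- min(cfg$chromosomes, length(pool))
  breaks <- sort(sample(seq_len(length(pool) - 1L), k - 1L))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(pool))
  chroms <- lapply(seq_len(k), function(i) {
    topo <- if (stats::runif(1) < cfg$circular_fraction) "circular" else "linear"
    chromosome(pool[starts[i]:ends[i]], signs[starts[i]:ends[i]], topo)
  })
  genome(name, chroms)
}

sample_weighted <- function(weights) {
  sample(names(weights), 1L, prob = weights)
}

random_dcj <- function(s) {
  els <- s$elements
  ne <- length(els)
  if (ne == 0L) return(NULL)
  two <- ne >= 2L && stats::runif(1) < 0.8
  if (!two) {
    # fission of one adjacency: {pq} -> {p, q}
    adj <- which(!vapply(els, is_telomere, logical(1)))
    if (!length(adj)) return(NULL)
    i <- sample(rep(adj, 2L), 1L)
    sl <- els[[i]]$slots
    return(new_op("DCJ", list(sl), list(sl[1L], sl[2L])))
  }
  idx <- sample(ne, 2L)
  e1 <- els[[idx[1L]]]$slots
  e2 <- els[[idx[2L]]]$slots
  if (length(e1) == 2L && length(e2) == 2L) {
    if (stats::runif(1) < 0.5) {
      prod <- list(c(e1[1L], e2[1L]), c(e1[2L], e2[2L]))
    } else {
      prod <- list(c(e1[1L], e2[2L]), c(e1[2L], e2[1L]))
    }
  } else if (length(e1) == 1L && length(e2) == 1L) {
    prod <- list(c(e1, e2))
  } else {
    p <- if (length(e1) == 2L) e1 else e2
    q <- if (length(e1) == 2L) e2 else e1
    if (stats::runif(1) < 0.5) {
      prod <- list(c(p[1L], q), p[2L])
    } else {
      prod <- list(p[1L], c(p[2L], q))
    }
  }
  new_op("DCJ", list(e1, e2), prod)
}

random_ins <- function(s, fresh_counter) {
  fams <- names(copy_numbers(s))
  gene <- if (length(fams) && stats::runif(1) < 0.5) {
    sample(rep(fams, 2L), 1L)
  } else {
    paste0("x", fresh_counter)
  }
  h <- ext(gene, "h"); t <- ext(gene, "t")
  els <- s$elements
  ne <- length(els)
  mode <- sample(4L, 1L)
  if (mode %in% c(1L, 2L) && ne > 0L) {
    i <- sample(rep(seq_len(ne), 2L), 1L)
    sl <- els[[i]]$slots
    if (length(sl) == 2L) {
      op <- new_op("INS", list(sl), list(c(sl[1L], t), c(h, sl[2L])), gene)
    } else {
      op <- new_op("INS", list(sl), list(c(sl, t), h), gene)
    }
  } else if (mode == 3L) {
    op <- new_op("INS", list(), list(c(t, h)), gene)
  } else {
    op <- new_op("INS", list(), list(t, h), gene)
  }
  op
}

random_del <- function(s) {
  cn <- copy_numbers(s)
  if (!length(cn)) return(NULL)
  gene <- sample(rep(names(cn), 2L), 1L)
  h <- ext(gene, "h"); t <- ext(gene, "t")
  els <- s$elements
  hs <- which(vapply(els, function(el) h %in% el$slots, logical(1)))
  ts <- which(vapply(els, function(el) t %in% el$slots, logical(1)))
  ih <- sample(rep(hs, 2L), 1L)
  # prefer a tail occurrence in the same element when the head element also
  # carries a tail (single-gene circular case), else any tail element
  it <- if (t %in% els[[ih]]$slots) ih else sample(rep(setdiff(ts, ih), 2L), 1L)
  if (ih == it) {
    return(new_op("DEL", list(els[[ih]]$slots), list(), gene))
  }
  eh <- els[[ih]]$slots
  et <- els[[it]]$slots
  rest <- c(drop_one(eh, h), drop_one(et, t))
  new_op("DEL", list(eh, et),
         if (length(rest)) list(rest) else list(), gene)
}

#' Apply a random operation history to a genome
#'
#' Samples `cfg$ops` operations (kinds drawn from `cfg$weights`), each a
#' valid rewrite-schema instance on the current adjacency set, then realizes
#' the result back into a genome. Inapplicable draws are resampled (and
#' counted in the log).
#'
#' @param g A [genome()].
#' @param cfg A [simulation_config()].
#' @return List with `genome`, `adjacency_set`, `log` (list of applied
#'   operations) and `resamples`.
#' @export
apply_random_operations <- function(g, cfg) {
  set.seed(cfg$seed + 500009L)
  s <- genome_to_adjacency_set(g)
  log <- list()
  fresh <- 1L
  resamples <- 0L
  guard <- 0L
  while (length(log) < cfg$ops) {
    guard <- guard + 1L
    if (guard > 100L * (cfg$ops + 1L)) {
      stop("could not sample an applicable operation", call. = FALSE)
    }
    kind <- sample_weighted(cfg$weights)
    op <- switch(kind,
                 DCJ = random_dcj(s),
                 INS = random_ins(s, fresh),
                 DEL = random_del(s))
    if (is.null(op)) { resamples <- resamples + 1L; next }
    if (op$kind == "INS" && startsWith(op$gene, "x")) fresh <- fresh + 1L
    s <- apply_operation(s, op)
    log[[length(log) + 1L]] <- op
  }
  out <- if (length(s$elements)) realize_genome(s, paste0(g$name, "_evolved")) else
    genome(paste0(g$name, "_evolved"))
  list(genome = out, adjacency_set = s, log = log, resamples = resamples)
}

#' Simulate a genome pair with a known history
#'
#' Convenience wrapper: draws a random genome and an evolved copy separated
#' by `cfg$ops` random operations, so the true edit distance is at most
#' `cfg$ops`.
#'
#' @param cfg A [simulation_config()].
#' @return List with `a`, `b` (genomes) and `log`.
#' @export
simulate_pair <- function(cfg) {
  a <- random_genome(cfg, name = "anc")
  ev <- apply_random_operations(a, cfg)
  list(a = a, b = ev$genome, log = ev$log)
}
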