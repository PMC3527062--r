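# Shared fixture builders: everything is generated in code.

g1 <- function(...) parse_genomes(c(...))[[1L]]

# the canonical small-instance suite configuration: families <= 6, copy
# number <= 3, mixed topologies, history length 1..5
suite_config <- function(seed) {
  simulation_config(families = 2L + (seed %% 5L), copy_rate = 0.4,
                    chromosomes = 1L + (seed %% 2L), circular_fraction = 0.5,
                    ops = 1L + (seed %% 5L), seed = seed, max_copies = 3L)
}

# tiny instances with telomeres for capped-vs-uncapped oracle comparisons
small_tel_config <- function(seed) {
  simulation_config(families = 2L + (seed %% 2L), copy_rate = 0.3,
                    chromosomes = 1L + (seed %% 2L), circular_fraction = 0.2,
                    ops = 1L + (seed %% 3L), seed = seed, max_copies = 2L)
}

# random duplicate-free equal-content genome pair
dupfree_pair <- function(seed, families = 7L, chromosomes = 2L) {
  set.seed(seed)
  fams <- paste0("g", seq_len(families))
  mk <- function(nm) {
    ord <- sample(fams)
    signs <- sample(c(-1L, 1L), families, replace = TRUE)
    k <- min(chromosomes, families)
    breaks <- sort(sample(seq_len(families - 1L), k - 1L))
    starts <- c(1L, breaks + 1L); ends <- c(breaks, families)
    genome(nm, lapply(seq_len(k), function(i) {
      chromosome(ord[starts[i]:ends[i]], signs[starts[i]:ends[i]],
                 if (stats::runif(1) < 0.5) "circular" else "linear")
    }))
  }
  list(a = mk("A"), b = mk("B"))
}

# unique label-preserving bijection (labels must have multiplicity one)
match_forced <- function(g) {
  vapply(seq_along(g$L$label), function(i) {
    hit <- which(g$R$label == g$L$label[i])
    stopifnot(length(hit) == 1L)
    hit
  }, integer(1))
}

expect_valid_scenario <- function(report) {
  sc <- build_scenario(report)
  v <- verify_scenario(report$s1, sc, report$s2)
  expect_true(isTRUE(v$ok), info = paste("scenario replay failed:", v$reason))
  expect_true(all(vapply(sc$ops, op_matches_schema, logical(1))))
  invisible(sc)
}
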