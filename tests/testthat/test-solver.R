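test_that("packing selects maximum disjoint candidate sets", {
  mk <- function(l, r) list(left = l, right = r, ghosts = 0L,
                            pairing = cbind(integer(0), integer(0)))
  # pairwise disjoint: all selected
  cands <- list(mk(c(1L, 2L), c(1L, 2L)), mk(c(3L, 4L), c(3L, 4L)))
  expect_length(pack_cycles(cands, "exact", nl = 10L)$selected, 2L)
  # chain 1-2-3: the two outer sets form the optimum
  chain <- list(mk(c(1L, 2L), c(1L, 2L)), mk(c(2L, 3L), c(2L, 3L)),
                mk(c(3L, 4L), c(3L, 4L)))
  sel <- pack_cycles(chain, "exact", nl = 10L)$selected
  expect_equal(sel, c(1L, 3L))
  # empty input
  expect_length(pack_cycles(list(), "exact", nl = 10L)$selected, 0L)
  # exact mode refuses oversized candidate collections
  many <- lapply(1:40, function(i) mk(c(i, i + 100L), c(i, i + 100L)))
  expect_error(pack_cycles(many, "exact", nl = 300L, exact_limit = 10L),
               "refused")
})

test_that("exact packing matches brute force on random candidate collections", {
  brute_max <- function(covers) {
    best <- 0L
    nc <- length(covers)
    for (mask in 0:(2^nc - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(nc) - 1L)) > 0L)
      used <- unlist(covers[sel])
      if (!anyDuplicated(used)) best <- max(best, length(sel))
    }
    best
  }
  for (seed in 1:15) {
    set.seed(seed)
    nc <- sample(3:9, 1)
    cands <- lapply(seq_len(nc), function(i) {
      ids <- sample(10L, 4L)
      list(left = ids[1:2], right = ids[3:4], ghosts = 0L,
           pairing = cbind(integer(0), integer(0)))
    })
    covers <- lapply(cands, function(cd) c(cd$left, cd$right + 10L))
    sel <- pack_cycles(cands, "exact", nl = 10L)$selected
    expect_equal(length(sel), brute_max(covers))
    # greedy + local search also reaches a valid (maximal) packing
    selg <- pack_cycles(cands, "greedy_local", swap_radius = 2L, nl = 10L)$selected
    expect_false(anyDuplicated(unlist(covers[selg])) > 0)
  }
})

test_that("completion always yields a valid decomposition with packed cycles intact", {
  for (seed in 1:25) {
    cfg <- suite_config(seed)
    sim <- simulate_pair(cfg)
    s1 <- genome_to_adjacency_set(sim$a)
    s2 <- genome_to_adjacency_set(sim$b)
    gp <- compute_ghosts(s1, s2)
    graph <- build_graph(cap_telomeres(s1, s2), gp)
    cands <- enumerate_helpful_4cycles(graph)
    pk <- pack_cycles(cands, "greedy_local", nl = length(graph$left))
    d <- complete_decomposition(graph, pk, cands)
    expect_true(validate_decomposition(graph, d)$ok)
    comps <- components_of(graph, d)
    # the packed 4-cycles all appear as helpful cycles: completion never
    # yields fewer helpful cycles than the packing size
    cls <- vapply(comps, `[[`, character(1), "classification")
    expect_gte(sum(cls == "helpful"), length(pk$selected))
  }
})

test_that("oracle reproduces hand-enumerable optima", {
  gs <- parse_genomes(c(">A", "a b )", ">B", "a -b )", ">C", "a |",
                        ">D", "a a |", ">E", "a b |"))
  expect_equal(edit_distance(gs$A, gs$B, method = "exact")$distance, 1L)
  r <- edit_distance(gs$E, gs$E, method = "exact")
  expect_equal(r$distance, 0L)
  r2 <- edit_distance(gs$C, gs$D, method = "exact")
  expect_equal(r2$distance, 1L)
  expect_equal(r2$n, 3)
  expect_error(exact_best_decomposition(r$graph, max_side = 1L), "size cap")
})

test_that("telomere recovery splits cycles at null edges by the case rules", {
  # odd-path case: identical single-gene linear genomes
  r <- edit_distance(g1(">A", "a |"), g1(">B", "a |"))
  cls <- vapply(r$recovered, `[[`, character(1), "classification")
  expect_setequal(cls, "odd")
  expect_equal(r$distance, 0L)
  # one-null-adjacency case: circular vs linear single gene -> one even path
  r2 <- edit_distance(g1(">A", "a )"), g1(">B", "a |"))
  cls2 <- vapply(r2$recovered, `[[`, character(1), "classification")
  expect_equal(cls2, "even")
  expect_equal(r2$recovered[[1]]$kind, "path")
  expect_equal(length(r2$recovered[[1]]$edge_labels), 2L)
  expect_equal(r2$distance, 1L)
  # cycles without nulls pass through unchanged
  r3 <- edit_distance(g1(">A", "a b )"), g1(">B", "a -b )"))
  expect_equal(vapply(r3$recovered, `[[`, character(1), "kind"), "cycle")
})

test_that("distance formula and bookkeeping guards", {
  mkc <- function(cls) list(classification = cls)
  expect_equal(distance_from_components(2, list(mkc("helpful")))$distance, 1L)
  expect_equal(distance_from_components(3, rep(list(mkc("helpful")), 3))$distance, 0L)
  expect_equal(distance_from_components(2, rep(list(mkc("odd")), 2))$distance, 1L)
  expect_error(distance_from_components(2, list(mkc("odd"))), "non-integer")
})

test_that("approx equals the independent classic walk on duplicate-free pairs", {
  for (seed in 1:60) {
    pr <- dupfree_pair(seed, families = 5L + (seed %% 4L))
    d_pipe <- edit_distance(pr$a, pr$b)$distance
    d_classic <- classic_dcj_distance(pr$a, pr$b)
    expect_equal(d_pipe, d_classic,
                 info = paste("duplicate-free mismatch at seed", seed))
  }
})

test_that("approx never beats the oracle and stays within ratio 1.5", {
  for (seed in 1:30) {
    cfg <- suite_config(seed)
    sim <- simulate_pair(cfg)
    ra <- edit_distance(sim$a, sim$b, packing = "exact")
    ro <- edit_distance(sim$a, sim$b, method = "exact", max_side = 40L)
    expect_gte(ra$distance, ro$distance)
    if (ro$distance > 0) expect_lte(ra$distance / ro$distance, 1.5)
    expect_gte(ro$distance, ro$t1_size + ro$t2_size)
    expect_gte(ra$distance, ra$t1_size + ra$t2_size)
  }
})

test_that("greedy_local packing gives a working end-to-end alternative", {
  for (seed in c(3L, 11L, 19L)) {
    cfg <- suite_config(seed)
    sim <- simulate_pair(cfg)
    r <- edit_distance(sim$a, sim$b, packing = "greedy_local", swap_radius = 2L)
    expect_valid_scenario(r)
  }
})
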