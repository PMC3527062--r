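graph_for <- function(a, b) {
  s1 <- genome_to_adjacency_set(a)
  s2 <- genome_to_adjacency_set(b)
  build_graph(cap_telomeres(s1, s2), compute_ghosts(s1, s2))
}

shared_labels <- function(graph, li, ri) {
  length(intersect(graph$left[[li]]$slots, graph$right[[ri]]$slots))
}

test_that("graph sides, n, and shared-extremity structure are correct", {
  g <- graph_for(g1(">A", "a b )"), g1(">B", "a -b )"))
  expect_equal(length(g$left), 2L)
  expect_equal(length(g$right), 2L)
  expect_equal(g$n, 2)
  for (i in 1:2) for (j in 1:2) expect_equal(shared_labels(g, i, j), 1L)

  # identical single-gene circular genomes: one element per side sharing two
  # extremities (a double edge)
  g2 <- graph_for(g1(">A", "a )"), g1(">B", "a )"))
  expect_equal(length(g2$left), 1L)
  expect_equal(shared_labels(g2, 1L, 1L), 2L)

  # "a |" vs "a a |": six extremities per side after capping and ghosts
  g3 <- graph_for(g1(">A", "a |"), g1(">B", "a a |"))
  expect_equal(g3$n, 3)
})

test_that("label imbalance is rejected", {
  s1 <- adjacency_set(list(adjacency("a:h", "a:t")))
  s2 <- adjacency_set(list(adjacency("b:h", "b:t")))
  cp <- cap_telomeres(s1, s2)
  expect_error(build_graph(cp, structure(list(t1 = list(), t2 = list()),
                                         class = "ghost_pair")),
               "imbalance")
})

test_that("decomposition validation catches totality and label violations", {
  g <- graph_for(g1(">A", "a b )"), g1(">B", "a -b )"))
  ns <- length(g$L$label)
  # the unique valid label-preserving bijection
  m <- vapply(seq_len(ns), function(i) {
    which(g$R$label == g$L$label[i])
  }, integer(1))
  expect_true(validate_decomposition(g, decomposition(m))$ok)
  bad <- m
  bad[1:2] <- bad[2:1]
  v <- validate_decomposition(g, decomposition(bad))
  expect_false(v$ok)
  expect_equal(v$violation, "label")
  v2 <- validate_decomposition(g, decomposition(rep(1L, ns)))
  expect_false(v2$ok)
  expect_equal(v2$violation, "totality")
})

test_that("components and classification follow the cycle/path rules", {
  # forced double-edge instance: one cycle of length 2
  g <- graph_for(g1(">A", "a )"), g1(">B", "a )"))
  comps <- components_of(g, decomposition(match_forced(g)))
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$length, 2L)
  expect_equal(comps[[1]]$classification, "helpful")

  # (a b) vs (a -b): one 4-cycle
  g2 <- graph_for(g1(">A", "a b )"), g1(">B", "a -b )"))
  comps2 <- components_of(g2, decomposition(match_forced(g2)))
  expect_length(comps2, 1L)
  expect_equal(comps2[[1]]$length, 4L)

  # identical linear genome, identity-style matching: three 2-cycles
  g3 <- graph_for(g1(">A", "a b |"), g1(">B", "a b |"))
  d3 <- complete_decomposition(g3, list(selected = integer(0), mode = "exact"))
  comps3 <- components_of(g3, d3)
  expect_equal(vapply(comps3, `[[`, integer(1), "length"), c(2L, 2L, 2L))
  expect_true(all(vapply(comps3, `[[`, character(1), "classification") ==
                    "helpful"))
})

test_that("classification thresholds: ghosts at l/2 make a cycle unhelpful", {
  mk <- function(len, ghosts) {
    list(kind = "cycle", length = len, ghosts_left = 0L, ghosts_right = ghosts)
  }
  expect_equal(classify_component(mk(2L, 0L)), "helpful")
  expect_equal(classify_component(mk(2L, 1L)), "unhelpful")
  expect_equal(classify_component(mk(6L, 2L)), "helpful")
  expect_equal(classify_component(mk(6L, 3L)), "unhelpful")
  expect_equal(classify_component(list(kind = "path", length = 1L)), "odd")
  expect_equal(classify_component(list(kind = "path", length = 2L)), "even")
})

test_that("helpful 4-cycle enumeration matches exhaustive expectations", {
  g <- graph_for(g1(">A", "a b )"), g1(">B", "a -b )"))
  cands <- enumerate_helpful_4cycles(g)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$ghosts, 0L)

  # single element per side: no 4-cycles
  g2 <- graph_for(g1(">A", "a )"), g1(">B", "a )"))
  expect_length(enumerate_helpful_4cycles(g2), 0L)

  # "a )" vs "a |": the null adjacency participates in exactly one candidate
  g3 <- graph_for(g1(">A", "a )"), g1(">B", "a |"))
  cands3 <- enumerate_helpful_4cycles(g3)
  expect_length(cands3, 1L)
  expect_equal(cands3[[1]]$ghosts, 0L)
})

test_that("any label-preserving bijection of a capped graph yields only cycles", {
  for (seed in 1:20) {
    cfg <- suite_config(seed)
    sim <- simulate_pair(cfg)
    r <- edit_distance(sim$a, sim$b)
    comps <- r$components
    expect_true(all(vapply(comps, `[[`, character(1), "kind") == "cycle"))
    expect_equal(sum(vapply(comps, `[[`, integer(1), "length")), 2 * r$n)
    # unhelpful cycles have exactly l/2 ghosts, all on one side, and no taus
    for (cm in comps) {
      if (cm$classification == "unhelpful") {
        expect_equal(cm$ghosts_left + cm$ghosts_right, cm$length / 2)
        expect_true(cm$ghosts_left == 0L || cm$ghosts_right == 0L)
        labs <- r$graph$L$label[cm$edges[, 1]]
        expect_false(any(labs == tau_label()))
      }
    }
  }
})
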