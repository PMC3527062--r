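test_that("parsing reads topology, orientation and duplicate copies", {
  gs <- parse_genomes(c(">A", "a b |", ">B", "a -b )", ">C", "a a b |"))
  expect_named(gs, c("A", "B", "C"))
  expect_equal(gs$A$chromosomes[[1]]$genes, c("a", "b"))
  expect_equal(gs$A$chromosomes[[1]]$topology, "linear")
  expect_equal(gs$B$chromosomes[[1]]$signs, c(1L, -1L))
  expect_equal(gs$B$chromosomes[[1]]$topology, "circular")
  expect_equal(gs$C$chromosomes[[1]]$genes, c("a", "a", "b"))
})

test_that("parsing accepts comments, blank lines and multi-line chromosomes", {
  gs <- parse_genomes(c(">A  ", "# comment", "", "a b", "-c | d )"))
  expect_length(gs$A$chromosomes, 2L)
  expect_equal(gs$A$chromosomes[[1]]$genes, c("a", "b", "c"))
  expect_equal(gs$A$chromosomes[[1]]$signs, c(1L, 1L, -1L))
})

test_that("parser rejects malformed documents", {
  expect_error(parse_genomes(c(">A", "TAU |")), "reserved")
  expect_error(parse_genomes(c(">A", "a b")), "terminator")
  expect_error(parse_genomes(c(">A", "|")), "empty chromosome")
  expect_error(parse_genomes(c("a b |")), "header")
})

test_that("write/parse round trip is the identity", {
  doc <- c(">A", "a -b |", "c )", ">B", "x x -y |")
  gs <- parse_genomes(doc)
  expect_identical(write_genomes(gs), doc)
  # empty genome writes header only
  expect_identical(write_genomes(genome("E")), ">E")
})

test_that("adjacency sets follow the junction/telomere construction", {
  s <- genome_to_adjacency_set(g1(">A", "a b |"))
  expect_setequal(aset_keys(adjacency_set(s$elements)),
                  c("a:t", "a:h~b:t", "b:h"))
  s2 <- genome_to_adjacency_set(g1(">A", "a b )"))
  expect_setequal(aset_keys(s2), c("a:h~b:t", "a:t~b:h"))
  s3 <- genome_to_adjacency_set(g1(">A", "a a |"))
  expect_equal(sort(aset_keys(s3)), c("a:h", "a:h~a:t", "a:t"))
  # circular singleton gene joins its own head and tail
  s4 <- genome_to_adjacency_set(g1(">A", "a )"))
  expect_equal(aset_keys(s4), "a:h~a:t")
})

test_that("element counts follow G + L with 2 telomeres per linear chromosome", {
  for (seed in 1:25) {
    cfg <- suite_config(seed)
    g <- random_genome(cfg)
    s <- genome_to_adjacency_set(g)
    nlin <- sum(vapply(g$chromosomes, function(ch) ch$topology == "linear",
                       logical(1)))
    gcount <- sum(lengths(lapply(g$chromosomes, `[[`, "genes")))
    expect_equal(telomere_count(s), 2L * nlin)
    expect_equal(length(s), gcount + nlin)
    expect_true(check_consistent(s))
  }
})

test_that("realization inverts adjacency-set construction", {
  # unique realizations
  s <- adjacency_set(list(adjacency("a:h", "b:t"), adjacency("b:h", "a:t")))
  g <- realize_genome(s)
  expect_true(aset_equal(genome_to_adjacency_set(g), s))
  s2 <- adjacency_set(list(telomere("a:t"), telomere("a:h")))
  g2 <- realize_genome(s2)
  expect_length(g2$chromosomes, 1L)
  expect_equal(g2$chromosomes[[1]]$topology, "linear")
  # ambiguous duplicate multiset still round-trips
  s3 <- adjacency_set(rep(list(adjacency("a:h", "b:t"), adjacency("b:h", "a:t")), 2))
  expect_true(aset_equal(genome_to_adjacency_set(realize_genome(s3)), s3))
})

test_that("realization round-trips random simulated adjacency sets", {
  for (seed in 1:40) {
    cfg <- suite_config(seed)
    s <- genome_to_adjacency_set(random_genome(cfg))
    expect_true(aset_equal(genome_to_adjacency_set(realize_genome(s)), s))
  }
})

test_that("realization is deterministic and rejects inconsistent input", {
  s <- genome_to_adjacency_set(random_genome(suite_config(7L)))
  expect_identical(write_genomes(realize_genome(s)),
                   write_genomes(realize_genome(s)))
  bad <- adjacency_set(list(telomere("a:t")))
  expect_error(realize_genome(bad), "inconsistent")
})
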