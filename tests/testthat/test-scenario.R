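test_that("per-component operation counts follow the cost formulas", {
  # helpful 2-cycle without ghosts: free
  r <- edit_distance(g1(">A", "a )"), g1(">B", "a )"))
  expect_length(component_operations(r$recovered[[1]]), 0L)
  # helpful 4-cycle without ghosts: one DCJ
  r2 <- edit_distance(g1(">A", "a b )"), g1(">B", "a -b )"))
  ops2 <- component_operations(r2$recovered[[1]])
  expect_length(ops2, 1L)
  expect_equal(ops2[[1]]$kind, "DCJ")
  # unhelpful 2-cycle with one ghost in T1: one deletion
  r3 <- edit_distance(g1(">A", "a b )"), g1(">B", "b )"), method = "exact")
  sc3 <- build_scenario(r3)
  kinds3 <- vapply(sc3$ops, `[[`, character(1), "kind")
  expect_equal(sum(kinds3 == "DEL"), 1L)
})

test_that("whole-cycle insertion bootstraps a circular gene first", {
  a <- g1(">A", "c )")
  b <- g1(">B", "c )", "a b )")
  r <- edit_distance(a, b, method = "exact")
  expect_equal(r$distance, 2L)
  sc <- build_scenario(r)
  kinds <- vapply(sc$ops, `[[`, character(1), "kind")
  expect_equal(unname(kinds), c("INS", "INS"))
  # first insertion has no operands (initial circular gene)
  first_ins <- sc$ops[[which(kinds == "INS")[1]]]
  expect_length(first_ins$consumed, 0L)
  v <- verify_scenario(r$s1, sc, r$s2)
  expect_true(v$ok)
})

test_that("apply_operation implements the rewrite schemas on multisets", {
  s <- adjacency_set(list(adjacency("a:h", "b:t"), adjacency("b:h", "a:t")))
  op <- list(kind = "DCJ", consumed = list(c("a:h", "b:t"), c("b:h", "a:t")),
             produced = list(c("a:h", "b:h"), c("b:t", "a:t")), gene = NA)
  s2 <- apply_operation(s, op)
  expect_setequal(aset_keys(s2), c("a:h~b:h", "a:t~b:t"))

  # insertion into a telomere
  st <- adjacency_set(list(telomere("a:h")))
  op2 <- list(kind = "INS", consumed = list("a:h"),
              produced = list(c("a:h", "a:t"), "a:h"), gene = "a")
  s3 <- apply_operation(st, op2)
  expect_equal(sort(aset_keys(s3)), c("a:h", "a:h~a:t"))

  # deletion of a circular singleton
  sd <- adjacency_set(list(adjacency("a:t", "a:h")))
  op3 <- list(kind = "DEL", consumed = list(c("a:t", "a:h")),
              produced = list(), gene = "a")
  expect_length(apply_operation(sd, op3), 0L)

  # consuming an absent element fails
  expect_error(apply_operation(st, op3), "not present")
})

test_that("schema checker accepts legal rewrites and rejects others", {
  expect_true(op_matches_schema(list(kind = "DCJ",
                                     consumed = list(c("a:h", "b:t"), c("b:h", "a:t")),
                                     produced = list(c("a:h", "b:h"), c("b:t", "a:t")))))
  expect_true(op_matches_schema(list(kind = "DCJ",
                                     consumed = list("a:h", "a:t"),
                                     produced = list(c("a:h", "a:t")))))
  expect_true(op_matches_schema(list(kind = "INS", gene = "a",
                                     consumed = list(),
                                     produced = list(c("a:t", "a:h")))))
  expect_true(op_matches_schema(list(kind = "DEL", gene = "a",
                                     consumed = list(c("p:h", "a:t"), c("a:h", "q:t")),
                                     produced = list(c("p:h", "q:t")))))
  # DCJ must conserve extremities
  expect_false(op_matches_schema(list(kind = "DCJ",
                                      consumed = list(c("a:h", "b:t")),
                                      produced = list(c("a:h", "c:t")))))
  # insertion must add exactly one head-tail pair
  expect_false(op_matches_schema(list(kind = "INS", gene = "a",
                                      consumed = list(),
                                      produced = list(c("a:t", "b:h")))))
})

test_that("scenarios replay to the target and satisfy the count law", {
  cases <- list(
    list(a = g1(">A", "a b |"), b = g1(">B", "a b |"), d = 0L),
    list(a = g1(">A", "a |"), b = g1(">B", "a a |"), d = 1L),
    list(a = g1(">A", "a b )"), b = g1(">B", "a -b )"), d = 1L)
  )
  for (cs in cases) {
    r <- edit_distance(cs$a, cs$b)
    expect_equal(r$distance, cs$d)
    sc <- expect_valid_scenario(r)
    expect_equal(length(sc$ops), cs$d)
    kinds <- table(factor(vapply(sc$ops, `[[`, character(1), "kind"),
                          levels = c("DCJ", "INS", "DEL")))
    expect_equal(unname(kinds[["DEL"]]), r$t1_size)
    expect_equal(unname(kinds[["INS"]]), r$t2_size)
  }
})

test_that("verification flags spurious operations and wrong targets", {
  r <- edit_distance(g1(">A", "a b )"), g1(">B", "a -b )"))
  sc <- build_scenario(r)
  # append a spurious extra DCJ: count law broken
  bad <- sc
  bad$ops <- c(bad$ops, list(list(kind = "DCJ",
                                  consumed = list(c("a:h", "b:h"), c("b:t", "a:t")),
                                  produced = list(c("a:h", "b:t"), c("b:h", "a:t")),
                                  gene = NA)))
  v <- verify_scenario(r$s1, bad, r$s2)
  expect_false(v$ok)
  # wrong target
  v2 <- verify_scenario(r$s1, sc, genome_to_adjacency_set(g1(">C", "a b )")))
  expect_false(v2$ok)
})

test_that("scenario tabulation lists one row per operation", {
  r <- edit_distance(g1(">A", "a |"), g1(">B", "a a |"))
  df <- as.data.frame(build_scenario(r))
  expect_equal(nrow(df), 1L)
  expect_equal(df$kind, "INS")
  expect_equal(df$gene, "a")
})
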