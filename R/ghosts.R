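# Content-difference ghosts and null-extremity telomere capping.
#
# Ghost adjacencies represent gene copies present in one genome but not the
# other: the multiset difference of extremities is paired head-with-tail
# within each family. Capping replaces every telomere x by the adjacency
# x-tau and pads the telomere-poorer side with tau-tau adjacencies, so the
# adjacency graph consists of cycles only.

#' Ghost adjacencies of a genome pair
#'
#' For each gene family with a copy-number surplus in one genome, that many
#' head-tail ghost adjacencies are produced on the surplus side: `t1` from
#' extremities of `s1` missing in `s2` (genes that must be deleted), `t2`
#' symmetrically (genes that must be inserted).
#'
#' @param s1,s2 Adjacency sets of the two genomes.
#' @return List with ghost element lists `t1` and `t2` (class `ghost_pair`).
#' @export
#' @examples
#' s1 <- genome_to_adjacency_set(parse_genomes(c(">A", "a b |"))$A)
#' s2 <- genome_to_adjacency_set(parse_genomes(c(">B", "a |"))$B)
#' compute_ghosts(s1, s2)
compute_ghosts <- function(s1, s2) {
  check_consistent(s1)
  check_consistent(s2)
  cn1 <- copy_numbers(s1)
  cn2 <- copy_numbers(s2)
  fams <- sort(unique(c(names(cn1), names(cn2))))
  n1 <- ifelse(fams %in% names(cn1), cn1[fams], 0L)
  n2 <- ifelse(fams %in% names(cn2), cn2[fams], 0L)
  mk <- function(fam, k) {
    rep(lapply(fam, function(f) adjacency(ext(f, "h"), ext(f, "t"), origin = "ghost")),
        times = k)
  }
  t1 <- list(); t2 <- list()
  for (i in seq_along(fams)) {
    if (n1[i] > n2[i]) t1 <- c(t1, mk(fams[i], n1[i] - n2[i]))
    if (n2[i] > n1[i]) t2 <- c(t2, mk(fams[i], n2[i] - n1[i]))
  }
  structure(list(t1 = t1, t2 = t2), class = "ghost_pair")
}

#' @export
print.ghost_pair <- function(x, ...) {
  cat("Ghost pair: |T1| =", length(x$t1), "(to delete), |T2| =",
      length(x$t2), "(to insert)\n")
  invisible(x)
}

cap_one <- function(s, n_null) {
  els <- lapply(s$elements, function(el) {
    if (is_telomere(el)) adjacency(el$slots, tau_label(), origin = "null-cap") else el
  })
  if (n_null > 0L) {
    els <- c(els, rep(list(adjacency(tau_label(), tau_label(), origin = "null-cap")),
                      n_null))
  }
  adjacency_set(els)
}

#' Cap telomeres with null extremities
#'
#' Replaces every telomere `x` by the adjacency `x`-tau on both sides and
#' adds `|k2 - k1|` tau-tau adjacencies to whichever side has fewer
#' telomeres (`2*k1`, `2*k2` telomeres in `s1`, `s2`). Afterwards both sides
#' have equal per-label slot counts and the adjacency graph decomposes into
#' cycles only; the edit distance is unchanged.
#'
#' @param s1,s2 Adjacency sets.
#' @return List (class `capped_pair`) with `s1_capped`, `s2_capped`, `k1`,
#'   `k2`. Capped elements carry origin `"null-cap"`.
#' @export
cap_telomeres <- function(s1, s2) {
  tel1 <- telomere_count(s1)
  tel2 <- telomere_count(s2)
  if (tel1 %% 2L || tel2 %% 2L) {
    stop("odd telomere count: inconsistent adjacency set", call. = FALSE)
  }
  k1 <- tel1 %/% 2L
  k2 <- tel2 %/% 2L
  structure(list(
    s1_capped = cap_one(s1, max(0L, k2 - k1)),
    s2_capped = cap_one(s2, max(0L, k1 - k2)),
    k1 = k1, k2 = k2
  ), class = "capped_pair")
}

#' @export
print.capped_pair <- function(x, ...) {
  cat("Capped pair: k1 =", x$k1, ", k2 =", x$k2,
      "; |S1'| =", length(x$s1_capped), ", |S2'| =", length(x$s2_capped), "\n")
  invisible(x)
}
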