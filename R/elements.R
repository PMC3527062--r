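# Core value types: extremities, graph elements (adjacencies / telomeres),
# and adjacency sets (multisets of elements).
#
# An extremity is encoded as a single string "<gene>:h" or "<gene>:t"; the
# null extremity used for telomere capping is the bare reserved token "TAU".
# A graph element holds 1 slot (telomere) or 2 slots (adjacency); the pair is
# unordered, so canonical keys sort the slots.

#' Null-extremity marker
#'
#' The reserved token used as the null extremity when telomeres are capped.
#' It is never a valid gene name.
#'
#' @return A length-one character string.
#' @export
tau_label <- function() "TAU"

is_tau <- function(x) x == "TAU"

#' Build an extremity label
#'
#' @param gene Gene-family name (character).
#' @param end `"h"` (head) or `"t"` (tail).
#' @return Character extremity label, e.g. `"a:h"`.
#' @export
#' @examples
#' ext("a", "h")
ext <- function(gene, end) {
  stopifnot(end %in% c("h", "t"))
  paste0(gene, ":", end)
}

#' Gene family of an extremity label
#' @param x Extremity label(s).
#' @return Character vector of gene names.
#' @export
ext_gene <- function(x) sub(":[ht]$", "", x)

#' End (`"h"`/`"t"`) of an extremity label
#' @param x Extremity label(s).
#' @return Character vector of ends.
#' @export
ext_end <- function(x) sub("^.*:", "", x)

#' Opposite end of an extremity
#' @param x Extremity label.
#' @return The other extremity of the same gene.
#' @keywords internal
ext_other <- function(x) {
  g <- ext_gene(x)
  ifelse(ext_end(x) == "h", ext(g, "t"), ext(g, "h"))
}

#' Construct an adjacency element
#'
#' An adjacency is an unordered pair of extremities; `adjacency(x, y)` equals
#' `adjacency(y, x)`.
#'
#' @param x,y Extremity labels.
#' @param origin One of `"regular"`, `"ghost"`, `"null-cap"`.
#' @return A graph element (list with `slots` and `origin`).
#' @export
adjacency <- function(x, y, origin = "regular") {
  list(slots = c(x, y), origin = origin)
}

#' Construct a telomere element
#'
#' @param x Extremity label.
#' @param origin Element origin tag.
#' @return A graph element with a single slot.
#' @export
telomere <- function(x, origin = "regular") {
  list(slots = x, origin = origin)
}

is_telomere <- function(el) length(el$slots) == 1L

#' Canonical key of an element (order-free, origin-free)
#' @param el A graph element.
#' @return Character key.
#' @keywords internal
element_key <- function(el) paste(sort(el$slots), collapse = "~")

#' Human-readable label of a graph element
#' @param el A graph element.
#' @return Character string (telomeres carry a trailing dot).
#' @export
element_label <- function(el) {
  if (is_telomere(el)) paste0(el$slots, ".") else paste(el$slots, collapse = " ")
}

#' Construct an adjacency set
#'
#' The multiset of adjacencies and telomeres of a genome (or an augmented /
#' capped variant of one).
#'
#' @param elements List of graph elements (see [adjacency()], [telomere()]).
#' @return Object of class `adjacency_set`.
#' @export
adjacency_set <- function(elements = list()) {
  structure(list(elements = elements), class = "adjacency_set")
}

#' @export
length.adjacency_set <- function(x) length(x$elements)

#' @export
print.adjacency_set <- function(x, ...) {
  keys <- vapply(x$elements, element_label, character(1))
  cat("Adjacency set with", length(keys), "elements:\n")
  if (length(keys)) cat(" ", paste(sort(keys), collapse = ", "), "\n")
  invisible(x)
}

#' Canonical element keys of an adjacency set
#'
#' One sorted, origin-free key per element occurrence (e.g. `"a:h~b:t"`,
#' `"a:t"` for a telomere); sorting these keys gives a canonical multiset
#' representation.
#'
#' @param s Adjacency set.
#' @return Character vector of element keys.
#' @export
aset_keys <- function(s) {
  vapply(s$elements, element_key, character(1))
}

#' Multiset equality of two adjacency sets
#'
#' Compares elements by their extremity content only (origin tags are
#' bookkeeping, not identity).
#'
#' @param s1,s2 Adjacency sets.
#' @return Logical.
#' @export
aset_equal <- function(s1, s2) {
  identical(sort(aset_keys(s1)), sort(aset_keys(s2)))
}

#' All extremity slot labels of an adjacency set
#' @param s Adjacency set.
#' @return Character vector (one entry per slot occurrence).
#' @keywords internal
aset_extremities <- function(s) {
  unlist(lapply(s$elements, function(el) el$slots), use.names = FALSE)
}

#' Per-family copy numbers of an adjacency set
#'
#' Counts head occurrences per gene family (a consistent set has equal head
#' and tail counts, one pair per gene copy). Null extremities are ignored.
#'
#' @param s Adjacency set.
#' @return Named integer vector of copy numbers.
#' @export
copy_numbers <- function(s) {
  xs <- aset_extremities(s)
  xs <- xs[!is_tau(xs)]
  if (!length(xs)) return(integer(0))
  heads <- xs[ext_end(xs) == "h"]
  tab <- table(ext_gene(heads))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Check structural consistency of an adjacency set
#'
#' A set realizable as a genome has, per family, equal head and tail counts,
#' and an even number of telomeres.
#'
#' @param s Adjacency set.
#' @param strict Error (default) or return `FALSE` on inconsistency.
#' @return `TRUE` invisibly, or `FALSE` when `strict = FALSE`.
#' @export
check_consistent <- function(s, strict = TRUE) {
  fail <- function(msg) {
    if (strict) stop(msg, call. = FALSE) else return(FALSE)
  }
  xs <- aset_extremities(s)
  xs <- xs[!is_tau(xs)]
  if (length(xs)) {
    g <- ext_gene(xs)
    e <- ext_end(xs)
    h <- table(factor(g[e == "h"], levels = unique(g)))
    t <- table(factor(g[e == "t"], levels = unique(g)))
    if (!all(h == t)) {
      return(fail("inconsistent adjacency set: unbalanced head/tail counts"))
    }
  }
  ntel <- sum(vapply(s$elements, is_telomere, logical(1)))
  if (ntel %% 2L != 0L) {
    return(fail("inconsistent adjacency set: odd telomere count"))
  }
  invisible(TRUE)
}

#' Number of telomeres in an adjacency set
#' @param s Adjacency set.
#' @return Integer count of 1-slot elements.
#' @export
telomere_count <- function(s) {
  sum(vapply(s$elements, is_telomere, logical(1)))
}
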