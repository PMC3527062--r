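# Gene-order genomes: plain-text parsing/writing and conversion to and from
# adjacency sets.
#
# Orientation convention: a gene written +g exposes its tail g:t on the left
# and its head g:h on the right; -g is the reverse.

RESERVED_TOKENS <- c("TAU", "|", ")", ">")

#' Construct a chromosome
#'
#' @param genes Character vector of gene-family names (one entry per copy).
#' @param signs Integer vector of +1/-1 orientations (default all +1).
#' @param topology `"linear"` or `"circular"`.
#' @return A `dcj_chromosome` object.
#' @export
chromosome <- function(genes, signs = rep(1L, length(genes)),
                       topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!length(genes)) stop("chromosome must contain at least one gene", call. = FALSE)
  stopifnot(length(signs) == length(genes), all(signs %in% c(-1L, 1L)))
  structure(list(genes = as.character(genes), signs = as.integer(signs),
                 topology = topology),
            class = "dcj_chromosome")
}

#' Construct a genome
#'
#' @param name Genome identifier.
#' @param chromosomes List of [chromosome()] objects.
#' @return A `dcj_genome` object.
#' @export
genome <- function(name, chromosomes = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, chromosomes = chromosomes), class = "dcj_genome")
}

#' @export
print.dcj_genome <- function(x, ...) {
  cat("Genome", x$name, "with", length(x$chromosomes), "chromosome(s)\n")
  for (ch in x$chromosomes) {
    tok <- paste0(ifelse(ch$signs < 0, "-", ""), ch$genes)
    cat(" ", paste(tok, collapse = " "),
        if (ch$topology == "linear") "|" else ")", "\n")
  }
  invisible(x)
}

check_gene_token <- function(gene) {
  if (!nzchar(gene)) stop("empty gene name", call. = FALSE)
  if (gene %in% RESERVED_TOKENS) {
    stop("reserved token used as gene name: ", gene, call. = FALSE)
  }
  if (grepl("[:~[:space:]]", gene) || startsWith(gene, "-")) {
    stop("invalid gene name: ", gene, call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse a gene-order document
#'
#' Reads genomes in the UniMoG-style plain-text format: `>name` header lines,
#' then whitespace-separated signed gene tokens; each chromosome ends with
#' `|` (linear) or `)` (circular). `#` starts a comment. Duplicate gene names
#' denote duplicate copies.
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @return Named list of [genome()] objects.
#' @export
#' @examples
#' gs <- parse_genomes(c(">A", "a -b |", "c )"))
#' gs$A
parse_genomes <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  pending <- list(genes = character(0), signs = integer(0))
  flush_genome <- function() {
    if (length(pending$genes)) {
      stop("chromosome without terminator in genome ",
           cur_name %||% "<unnamed>", call. = FALSE)
    }
    if (!is.null(cur_name)) {
      genomes[[cur_name]] <<- genome(cur_name, cur_chroms)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush_genome()
      cur_name <- trimws(substring(ln, 2))
      if (!nzchar(cur_name)) stop("empty genome name", call. = FALSE)
      cur_chroms <- list()
      pending <- list(genes = character(0), signs = integer(0))
      next
    }
    if (is.null(cur_name)) stop("gene data before any '>' header", call. = FALSE)
    for (tok in strsplit(ln, "[[:space:]]+")[[1]]) {
      if (tok %in% c("|", ")")) {
        if (!length(pending$genes)) {
          stop("empty chromosome in genome ", cur_name, call. = FALSE)
        }
        topo <- if (tok == "|") "linear" else "circular"
        cur_chroms[[length(cur_chroms) + 1L]] <-
          chromosome(pending$genes, pending$signs, topo)
        pending <- list(genes = character(0), signs = integer(0))
      } else {
        sgn <- 1L
        if (startsWith(tok, "-")) {
          sgn <- -1L
          tok <- substring(tok, 2)
        }
        check_gene_token(tok)
        pending$genes <- c(pending$genes, tok)
        pending$signs <- c(pending$signs, sgn)
      }
    }
  }
  flush_genome()
  genomes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write genomes as a gene-order document
#'
#' Inverse of [parse_genomes()]: `parse_genomes(write_genomes(g))` reproduces
#' the input genomes.
#'
#' @param genomes A single genome or a list of genomes.
#' @return Character vector of document lines.
#' @export
write_genomes <- function(genomes) {
  if (inherits(genomes, "dcj_genome")) genomes <- list(genomes)
  out <- character(0)
  for (g in genomes) {
    out <- c(out, paste0(">", g$name))
    for (ch in g$chromosomes) {
      tok <- paste0(ifelse(ch$signs < 0, "-", ""), ch$genes)
      out <- c(out, paste(c(tok, if (ch$topology == "linear") "|" else ")"),
                          collapse = " "))
    }
  }
  out
}

#' Adjacency set of a genome
#'
#' One adjacency per pair of consecutive genes (the extremities facing the
#' junction) and one telomere per end of each linear chromosome. A circular
#' chromosome of length one yields the adjacency of its gene's own head and
#' tail.
#'
#' @param g A [genome()].
#' @return An [adjacency_set()].
#' @export
#' @examples
#' g <- parse_genomes(c(">A", "a b |"))$A
#' genome_to_adjacency_set(g)
genome_to_adjacency_set <- function(g) {
  els <- list()
  for (ch in g$chromosomes) {
    m <- length(ch$genes)
    left <- ifelse(ch$signs > 0, ext(ch$genes, "t"), ext(ch$genes, "h"))
    right <- ifelse(ch$signs > 0, ext(ch$genes, "h"), ext(ch$genes, "t"))
    if (ch$topology == "linear") {
      els[[length(els) + 1L]] <- telomere(left[1])
      if (m > 1L) {
        for (i in seq_len(m - 1L)) {
          els[[length(els) + 1L]] <- adjacency(right[i], left[i + 1L])
        }
      }
      els[[length(els) + 1L]] <- telomere(right[m])
    } else {
      for (i in seq_len(m)) {
        j <- if (i == m) 1L else i + 1L
        els[[length(els) + 1L]] <- adjacency(right[i], left[j])
      }
    }
  }
  adjacency_set(els)
}

#' Realize an adjacency set as a genome
#'
#' Reconstructs one genome whose adjacency set equals `s`. With duplicate
#' genes the genomic structure may be ambiguous; a deterministic tie-break is
#' used: linear chromosomes are grown from the lexicographically smallest
#' unused telomere, circular ones from the smallest unused extremity, always
#' consuming the smallest matching element occurrence.
#'
#' @param s A consistent [adjacency_set()] (real elements only, no null
#'   extremities).
#' @param name Name for the realized genome.
#' @return A [genome()] with `genome_to_adjacency_set(result)` equal to `s`.
#' @export
realize_genome <- function(s, name = "realized") {
  check_consistent(s)
  if (any(is_tau(aset_extremities(s)))) {
    stop("cannot realize a capped adjacency set (contains null extremities)",
         call. = FALSE)
  }
  els <- s$elements
  ne <- length(els)
  if (!ne) return(genome(name))
  ord <- order(vapply(els, element_key, character(1)), seq_len(ne))
  els <- els[ord]
  # slot table in deterministic order
  slot_elem <- integer(0); slot_pos <- integer(0); slot_label <- character(0)
  for (i in seq_len(ne)) {
    sl <- sort(els[[i]]$slots)
    slot_elem <- c(slot_elem, rep(i, length(sl)))
    slot_pos <- c(slot_pos, seq_along(sl))
    slot_label <- c(slot_label, sl)
  }
  used_slot <- rep(FALSE, length(slot_label))
  elem_slot_ids <- split(seq_along(slot_label), slot_elem)
  is_tel <- vapply(els, is_telomere, logical(1))

  take_slot <- function(label, forbid_elem = 0L) {
    cand <- which(!used_slot & slot_label == label & slot_elem != forbid_elem)
    if (!length(cand)) return(NA_integer_)
    cand[1L]
  }
  other_slot <- function(sid) {
    ids <- elem_slot_ids[[as.character(slot_elem[sid])]]
    setdiff(ids, sid)
  }

  chroms <- list()
  # linear chromosomes: start from smallest unused telomere
  repeat {
    tel_slots <- which(!used_slot & is_tel[slot_elem])
    if (!length(tel_slots)) break
    start <- tel_slots[order(slot_label[tel_slots], tel_slots)][1L]
    used_slot[start] <- TRUE
    genes <- character(0); signs <- integer(0)
    x <- slot_label[start]
    repeat {
      genes <- c(genes, ext_gene(x))
      signs <- c(signs, if (ext_end(x) == "t") 1L else -1L)
      nxt <- take_slot(ext_other(x))
      stopifnot(!is.na(nxt))
      used_slot[nxt] <- TRUE
      if (is_tel[slot_elem[nxt]]) break
      os <- other_slot(nxt)
      used_slot[os] <- TRUE
      x <- slot_label[os]
    }
    chroms[[length(chroms) + 1L]] <- chromosome(genes, signs, "linear")
  }
  # circular chromosomes from what remains
  repeat {
    free <- which(!used_slot)
    if (!length(free)) break
    start <- free[order(slot_label[free], free)][1L]
    e0 <- slot_elem[start]
    used_slot[start] <- TRUE
    genes <- character(0); signs <- integer(0)
    x <- slot_label[start]
    repeat {
      genes <- c(genes, ext_gene(x))
      signs <- c(signs, if (ext_end(x) == "t") 1L else -1L)
      # prefer closing into the start element once its remaining slot matches
      closing <- which(!used_slot & slot_label == ext_other(x) & slot_elem == e0)
      nxt <- if (length(closing)) closing[1L] else take_slot(ext_other(x), forbid_elem = e0)
      if (is.na(nxt)) stop("inconsistent multiset: no realization exists", call. = FALSE)
      used_slot[nxt] <- TRUE
      if (slot_elem[nxt] == e0) break
      os <- other_slot(nxt)
      used_slot[os] <- TRUE
      x <- slot_label[os]
    }
    chroms[[length(chroms) + 1L]] <- chromosome(genes, signs, "circular")
  }
  genome(name, chroms)
}
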