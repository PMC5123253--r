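#' Signed circular genomes
#'
#' A genome is a multiset of circular chromosomes, each a cyclic sequence of
#' signed genes. Two chromosomes are considered equal when one is a rotation
#' of the other, or a rotation of the other's reversal with every strand
#' flipped -- a circular DNA molecule has no preferred reading direction.
#' A genome is *ordinary* when every gene occurs exactly once, and
#' *all-duplicated* when every gene occurs exactly twice.
#'
#' @param chromosomes a list of chromosomes; each chromosome is a list with
#'   components `genes` (character vector of gene names) and `signs`
#'   (integer vector of +1/-1 of the same length).
#' @return an object of class `"genome"`.
#' @examples
#' g <- genome(list(list(genes = c("a", "b"), signs = c(1L, -1L))))
#' write_genome(g)
#' @export
genome <- function(chromosomes) {
  if (!is.list(chromosomes) || length(chromosomes) == 0L)
    stop2("a genome needs at least one chromosome")
  chromosomes <- lapply(chromosomes, function(ch) {
    genes <- as.character(ch$genes)
    signs <- as.integer(ch$signs)
    if (length(genes) == 0L) stop2("empty chromosome")
    if (length(genes) != length(signs)) stop2("genes and signs lengths differ")
    if (!all(signs %in% c(-1L, 1L))) stop2("signs must be +1 or -1")
    bad <- !grepl("^[A-Za-z0-9_]+$", genes)
    if (any(bad)) stop2("illegal gene token: ", genes[bad][1L])
    list(genes = genes, signs = signs)
  })
  structure(list(chromosomes = chromosomes), class = "genome")
}

chrom_tokens <- function(ch) {
  paste0(ifelse(ch$signs > 0L, "+", "-"), ch$genes)
}

# All rotations of the chromosome plus all rotations of its reflection
# (reversed gene order with flipped strands), as token vectors.
chrom_variants <- function(ch) {
  n <- length(ch$genes)
  refl <- list(genes = rev(ch$genes), signs = -rev(ch$signs))
  vars <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    idx <- c(i:n, seq_len(i - 1L))[seq_len(n)]
    vars[[i]] <- chrom_tokens(list(genes = ch$genes[idx], signs = ch$signs[idx]))
    vars[[n + i]] <- chrom_tokens(list(genes = refl$genes[idx], signs = refl$signs[idx]))
  }
  vars
}

# Canonical token vector: lexicographically smallest variant in C-locale
# byte order; "+" sorts before "-", so the smallest gene comes first on the
# "+" strand whenever some variant allows it.
chrom_canonical_tokens <- function(ch) {
  vars <- chrom_variants(ch)
  keys <- vapply(vars, paste, character(1), collapse = "")
  vars[[corder(keys)[1L]]]
}

tokens_to_chrom <- function(tokens) {
  signs <- ifelse(substr(tokens, 1L, 1L) == "-", -1L, 1L)
  genes <- sub("^[+-]", "", tokens)
  list(genes = genes, signs = signs)
}

#' Canonicalize a genome
#'
#' Rotates/reflects every chromosome to its canonical reading and sorts the
#' chromosomes lexicographically. Two genomes are equal iff their canonical
#' forms are identical.
#'
#' @param g a [genome()].
#' @return a `"genome"` in canonical form.
#' @export
canonical_genome <- function(g) {
  stopifnot(inherits(g, "genome"))
  toks <- lapply(g$chromosomes, chrom_canonical_tokens)
  keys <- vapply(toks, paste, character(1), collapse = "")
  toks <- toks[corder(keys)]
  genome(lapply(toks, tokens_to_chrom))
}

#' @export
print.genome <- function(x, ...) {
  cat(write_genome(x), "\n")
  invisible(x)
}

#' Test two genomes for equality
#'
#' @param a,b genomes.
#' @return logical.
#' @export
genomes_equal <- function(a, b) {
  identical(write_genome(a), write_genome(b))
}

genome_key <- function(g) write_genome(g)

#' Gene content of a genome
#'
#' @param g a genome.
#' @return named integer vector: occurrence count per distinct gene name.
#' @export
gene_multiplicity <- function(g) {
  stopifnot(inherits(g, "genome"))
  all_genes <- unlist(lapply(g$chromosomes, `[[`, "genes"))
  tab <- table(all_genes)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[csort(names(out))]
}

#' @rdname gene_multiplicity
#' @export
gene_names <- function(g) csort(names(gene_multiplicity(g)))

#' @rdname gene_multiplicity
#' @export
n_genes <- function(g) length(gene_names(g))

#' Ordinary / all-duplicated predicates
#'
#' An ordinary genome has every gene in one copy; an all-duplicated genome
#' (the typical state right after a whole-genome duplication, up to
#' rearrangement) has every gene in exactly two copies.
#'
#' @param g a genome.
#' @return logical.
#' @export
is_ordinary <- function(g) all(gene_multiplicity(g) == 1L)

#' @rdname is_ordinary
#' @export
is_all_duplicated <- function(g) all(gene_multiplicity(g) == 2L)

#' Parse a genome from text
#'
#' Two dialects are supported. The `"paper"` dialect is a concatenation of
#' parenthesized circular chromosomes such as `"(+a+d-c-b)(+e)"`; whitespace
#' is ignored and the Unicode minus sign is accepted. The `"grimm"` dialect
#' has one chromosome per line, whitespace-separated signed gene tokens
#' terminated by `"@"` (circular); an optional `">name"` header line is
#' skipped. Linear chromosomes (`"$"`-terminated) are rejected.
#'
#' @param text a character scalar (or vector of lines for `"grimm"`).
#' @param dialect `"paper"` or `"grimm"`.
#' @return a [genome()].
#' @examples
#' parse_genome("(+a+d-c-b)")
#' parse_genome("a d -c -b @", dialect = "grimm")
#' @export
parse_genome <- function(text, dialect = c("paper", "grimm")) {
  dialect <- match.arg(dialect)
  text <- gsub("−", "-", text)
  if (dialect == "paper") parse_genome_paper(text) else parse_genome_grimm(text)
}

parse_genome_paper <- function(text) {
  s <- gsub("[[:space:]]", "", paste(text, collapse = ""))
  if (s == "") stop2("empty genome text")
  if (!grepl("^(\\([^()]*\\))+$", s)) {
    if (grepl("\\$", s)) stop2("linear chromosomes unsupported")
    stop2("unbalanced parentheses or stray text in genome string")
  }
  bodies <- regmatches(s, gregexpr("\\(([^()]*)\\)", s))[[1]]
  bodies <- substr(bodies, 2L, nchar(bodies) - 1L)
  chroms <- lapply(bodies, function(b) {
    if (b == "") stop2("empty chromosome")
    toks <- regmatches(b, gregexpr("[+-][A-Za-z0-9_]+", b))[[1]]
    if (paste(toks, collapse = "") != b)
      stop2("illegal gene token in chromosome '(", b, ")'")
    tokens_to_chrom(toks)
  })
  genome(chroms)
}

parse_genome_grimm <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, ">")]
  if (length(lines) == 0L) stop2("empty genome text")
  chroms <- lapply(lines, function(line) {
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    if (toks[length(toks)] == "$") stop2("linear chromosomes unsupported")
    if (toks[length(toks)] != "@")
      stop2("grimm chromosome line must end with '@'")
    toks <- toks[-length(toks)]
    if (length(toks) == 0L) stop2("empty chromosome")
    ok <- grepl("^[+-]?[A-Za-z0-9_]+$", toks)
    if (!all(ok)) stop2("illegal gene token: ", toks[!ok][1L])
    toks <- ifelse(grepl("^[+-]", toks), toks, paste0("+", toks))
    tokens_to_chrom(toks)
  })
  genome(chroms)
}

#' Write a genome to text
#'
#' Output is canonical (see [canonical_genome()]), so
#' `parse_genome(write_genome(g))` reproduces `g` up to chromosome
#' rotation/reflection. The GRIMM dialect omits "+" signs and terminates each
#' circular chromosome with `"@"`.
#'
#' @param g a genome.
#' @param dialect `"paper"` or `"grimm"`.
#' @return a character scalar.
#' @export
write_genome <- function(g, dialect = c("paper", "grimm")) {
  dialect <- match.arg(dialect)
  gc <- canonical_genome_chrom_tokens(g)
  if (dialect == "paper") {
    paste(vapply(gc, function(t) paste0("(", paste(t, collapse = ""), ")"),
                 character(1)), collapse = "")
  } else {
    paste(vapply(gc, function(t) {
      paste(c(sub("^\\+", "", t), "@"), collapse = " ")
    }, character(1)), collapse = "\n")
  }
}

canonical_genome_chrom_tokens <- function(g) {
  stopifnot(inherits(g, "genome"))
  toks <- lapply(g$chromosomes, chrom_canonical_tokens)
  keys <- vapply(toks, paste, character(1), collapse = "")
  toks[corder(keys)]
}

#' Gene extremities
#'
#' Every gene `x` has a tail extremity `x.t` and a head extremity `x.h`.
#' Traversing `+x` enters at `x.t` and exits at `x.h`; traversing `-x` enters
#' at `x.h` and exits at `x.t`.
#'
#' @param genes character vector of gene names.
#' @return character vector of the `2 * length(genes)` extremities, sorted.
#' @export
extremities <- function(genes) {
  csort(c(paste0(genes, ".t"), paste0(genes, ".h")))
}

ext_gene <- function(e) sub("\\.[th]$", "", e)
ext_end <- function(e) substring(e, nchar(e), nchar(e))
ext_other <- function(e) {
  ifelse(ext_end(e) == "t", paste0(ext_gene(e), ".h"), paste0(ext_gene(e), ".t"))
}

#' Adjacencies of a genome
#'
#' One adjacency per pair of consecutive genes on each circular chromosome,
#' joining the exit extremity of a gene to the entry extremity of its
#' successor. For an ordinary genome the adjacencies form a perfect matching
#' on the `2n` extremities; for a duplicated genome they form a multiset.
#'
#' @param g a genome.
#' @return a 2-column character matrix of extremity pairs (rows sorted,
#'   canonical order, duplicates kept).
#' @examples
#' adjacencies(parse_genome("(+a+d-c-b)"))
#' @export
adjacencies <- function(g) {
  stopifnot(inherits(g, "genome"))
  pairs <- list()
  for (ch in g$chromosomes) {
    n <- length(ch$genes)
    enter <- ifelse(ch$signs > 0L, paste0(ch$genes, ".t"), paste0(ch$genes, ".h"))
    exit <- ifelse(ch$signs > 0L, paste0(ch$genes, ".h"), paste0(ch$genes, ".t"))
    nxt <- if (n == 1L) 1L else c(2:n, 1L)
    for (i in seq_len(n)) {
      pairs[[length(pairs) + 1L]] <- c(exit[i], enter[nxt[i]])
    }
  }
  as_adj_matrix(pairs)
}

#' Reconstruct an ordinary genome from an adjacency matching
#'
#' The inverse of [adjacencies()] for ordinary genomes: given a perfect
#' matching on the extremities of a gene set, alternate matching edges with
#' gene (tail--head) edges to recover the circular chromosomes.
#'
#' @param m a 2-column character matrix (or list of pairs) of extremities.
#' @return an ordinary [genome()] with `adjacencies(result)` equal to `m`.
#' @export
genome_from_matching <- function(m) {
  m <- as_adj_matrix(m)
  verts <- c(m[, 1L], m[, 2L])
  if (anyDuplicated(verts)) stop2("not a perfect matching: repeated extremity")
  genes <- unique(ext_gene(verts))
  expected <- extremities(genes)
  if (!identical(csort(verts), expected))
    stop2("not a perfect matching on the extremities of a gene set")
  partner <- c(stats::setNames(m[, 2L], m[, 1L]), stats::setNames(m[, 1L], m[, 2L]))
  used <- stats::setNames(rep(FALSE, length(genes)), genes)
  chroms <- list()
  for (start_gene in csort(genes)) {
    if (used[[start_gene]]) next
    entry <- paste0(start_gene, ".t")
    gs <- character(0)
    ss <- integer(0)
    repeat {
      gene <- ext_gene(entry)
      sign <- if (ext_end(entry) == "t") 1L else -1L
      gs <- c(gs, gene)
      ss <- c(ss, sign)
      used[[gene]] <- TRUE
      exit <- ext_other(entry)
      entry <- unname(partner[[exit]])
      if (ext_gene(entry) == start_gene) break
    }
    chroms[[length(chroms) + 1L]] <- list(genes = gs, signs = ss)
  }
  canonical_genome(genome(chroms))
}
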