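# Internal helpers shared across modules. All ordering is done in C-locale
# radix order so canonical forms do not depend on the session locale.

csort <- function(x) sort(x, method = "radix")

corder <- function(...) order(..., method = "radix")

#' @noRd
stop2 <- function(...) stop(..., call. = FALSE)

# Canonical key for an unordered extremity pair.
adj_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "--")
}

# Normalise an adjacency list/matrix into a 2-column character matrix with
# each row sorted and rows in canonical order. Duplicated rows (multiset
# semantics) are preserved.
as_adj_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else if (is.list(x)) {
    if (length(x) == 0L) {
      m <- matrix(character(0), ncol = 2)
    } else {
      m <- do.call(rbind, lapply(x, function(p) {
        if (length(p) != 2L) stop2("an adjacency must have exactly 2 extremities")
        as.character(p)
      }))
    }
  } else {
    stop2("adjacencies must be a 2-column matrix or a list of pairs")
  }
  if (ncol(m) != 2L) stop2("adjacencies must have 2 columns")
  if (nrow(m) > 0L) {
    swap <- m[, 1L] > m[, 2L]
    tmp <- m[swap, 1L]
    m[swap, 1L] <- m[swap, 2L]
    m[swap, 2L] <- tmp
    m <- m[corder(m[, 1L], m[, 2L]), , drop = FALSE]
  }
  dimnames(m) <- NULL
  m
}

# Union-find with path compression (small instances; plain R is fine).
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

uf_classes <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

# Enumerate all perfect matchings on a set of items (by index), fixing the
# lowest unmatched index first so each matching is produced exactly once.
# Returns a list of 2-column integer matrices.
enumerate_perfect_matchings <- function(n) {
  if (n %% 2L != 0L) stop2("cannot perfectly match an odd number of items")
  out <- list()
  recurse <- function(free, acc) {
    if (length(free) == 0L) {
      out[[length(out) + 1L]] <<- acc
      return(invisible(NULL))
    }
    first <- free[1L]
    rest <- free[-1L]
    for (j in seq_along(rest)) {
      recurse(rest[-j], rbind(acc, c(first, rest[j])))
    }
  }
  recurse(seq_len(n), matrix(integer(0), ncol = 2))
  out
}

# Exact binomial coefficient as a base double (exact below 2^53, which covers
# every count this package produces at desk scale).
exact_choose <- function(n, k) {
  if (k < 0 || k > n) return(0)
  round(choose(n, k))
}
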