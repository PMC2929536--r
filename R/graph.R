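# Triple container with set semantics. Subjects are absolute IRIs or blank-node
# ids ("_:" prefix); predicates are absolute IRIs; objects are IRIs, blank-node
# ids, or plain literals (the schema never types its literals). Stored as a
# data.frame with columns s, p, o, o_lit.

empty_triples <- function() {
  data.frame(s = character(), p = character(), o = character(),
             o_lit = logical(), stringsAsFactors = FALSE)
}

triple_key <- function(df) {
  paste(df$s, df$p, df$o, df$o_lit, sep = "\r")
}

is_blank <- function(x) startsWith(x, "_:")

#' Create an empty TMA graph
#'
#' A `tma_graph` is a set of subject-predicate-object statements together with
#' a namespace map. Duplicate statements collapse to one triple.
#'
#' @param nsmap A [tma_nsmap()]; defaults to [default_nsmap()].
#' @return An object of class `tma_graph`.
#' @export
tma_graph <- function(nsmap = default_nsmap()) {
  structure(list(triples = empty_triples(), nsmap = nsmap), class = "tma_graph")
}

#' Add triples to a graph
#'
#' Terms must already be absolute IRIs or `_:` blank ids; literals are flagged
#' with `o_lit`. Duplicates (set semantics) are dropped silently.
#'
#' @param graph A `tma_graph`.
#' @param s,p,o Character vectors (recycled to common length).
#' @param o_lit Logical vector: is the object a literal?
#' @return The updated graph.
#' @export
add_triples <- function(graph, s, p, o, o_lit = FALSE) {
  stopifnot(inherits(graph, "tma_graph"))
  n <- max(length(s), length(p), length(o), length(o_lit))
  new <- data.frame(s = rep_len(as.character(s), n),
                    p = rep_len(as.character(p), n),
                    o = rep_len(as.character(o), n),
                    o_lit = rep_len(as.logical(o_lit), n),
                    stringsAsFactors = FALSE)
  all <- rbind(graph$triples, new)
  graph$triples <- all[!duplicated(triple_key(all)), , drop = FALSE]
  rownames(graph$triples) <- NULL
  graph
}

graph_size <- function(graph) nrow(graph$triples)

#' @export
print.tma_graph <- function(x, ...) {
  cat(sprintf("<tma_graph> %d triple(s)\n", nrow(x$triples)))
  invisible(x)
}

# Deterministic blank-node relabeling: each blank node is keyed by the sorted
# set of its incident triples with blank positions masked, ties broken by first
# occurrence. Enough for the few blank nodes these documents carry.
blank_signatures <- function(df) {
  blanks <- unique(c(df$s[is_blank(df$s)], df$o[!df$o_lit & is_blank(df$o)]))
  if (!length(blanks)) return(character())
  sig <- vapply(blanks, function(b) {
    inc <- df[df$s == b | (!df$o_lit & df$o == b), , drop = FALSE]
    s <- ifelse(is_blank(inc$s), "~", inc$s)
    o <- ifelse(!inc$o_lit & is_blank(inc$o), "~", inc$o)
    lines <- sort(paste(s, inc$p, o, inc$o_lit, sep = "\r"), method = "radix")
    paste(lines, collapse = "\n")
  }, character(1))
  ord <- order(sig, match(blanks, blanks), method = "radix")
  labels <- paste0("_:c", seq_along(blanks))
  names(labels) <- blanks[ord]
  labels
}

#' Canonically ordered triples
#'
#' Returns the graph's triples sorted lexicographically (byte order) by
#' subject, predicate, object, with blank nodes deterministically relabeled.
#' The ordering is invariant under permutation of the input.
#'
#' @param graph A `tma_graph`.
#' @return A data.frame with columns `s`, `p`, `o`, `o_lit`.
#' @export
canonical_triples <- function(graph) {
  df <- graph$triples
  relab <- blank_signatures(df)
  if (length(relab)) {
    hit <- df$s %in% names(relab)
    df$s[hit] <- relab[df$s[hit]]
    hit <- !df$o_lit & df$o %in% names(relab)
    df$o[hit] <- relab[df$o[hit]]
  }
  df <- df[!duplicated(triple_key(df)), , drop = FALSE]
  df <- df[order(df$s, df$p, df$o_lit, df$o, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Graph isomorphism up to blank-node relabeling
#'
#' Two graphs are isomorphic when some bijection over their blank-node ids
#' maps one triple set exactly onto the other. Ground triples must match
#' byte-for-byte; blank nodes are matched by exhaustive search (documents here
#' carry at most a handful).
#'
#' @param g1,g2 `tma_graph` objects.
#' @return Logical scalar.
#' @export
graph_isomorphic <- function(g1, g2) {
  d1 <- g1$triples[!duplicated(triple_key(g1$triples)), , drop = FALSE]
  d2 <- g2$triples[!duplicated(triple_key(g2$triples)), , drop = FALSE]
  if (nrow(d1) != nrow(d2)) return(FALSE)
  b1 <- unique(c(d1$s[is_blank(d1$s)], d1$o[!d1$o_lit & is_blank(d1$o)]))
  b2 <- unique(c(d2$s[is_blank(d2$s)], d2$o[!d2$o_lit & is_blank(d2$o)]))
  if (length(b1) != length(b2)) return(FALSE)
  key2 <- sort(triple_key(d2), method = "radix")
  same_under <- function(map) {
    s <- d1$s; o <- d1$o
    hit <- s %in% names(map); s[hit] <- map[s[hit]]
    hit <- !d1$o_lit & o %in% names(map); o[hit] <- map[o[hit]]
    identical(sort(paste(s, d1$p, o, d1$o_lit, sep = "\r"), method = "radix"), key2)
  }
  if (!length(b1)) return(same_under(character()))
  if (length(b1) > 8L) {
    # fall back to canonical labeling for larger blank populations
    c1 <- canonical_triples(g1); c2 <- canonical_triples(g2)
    return(identical(triple_key(c1), triple_key(c2)))
  }
  for (perm in perms(length(b1))) {
    map <- stats::setNames(b2[perm], b1)
    if (same_under(map)) return(TRUE)
  }
  FALSE
}

# all permutations of 1..n as a list (n small)
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in perms(n - 1L)) {
      v <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, v[rest])
    }
  }
  out
}
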