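# Reading and writing TMA instance documents. RDF/XML is the primary format;
# Turtle is offered for readability and N-Triples for canonical diffs. Output
# is deterministic: triples are emitted in canonical order and only the
# prefixes actually used are declared. Literals are carried as plain strings
# with no datatype coercion ("78,90" is never reformatted).

RDF_FORMATS <- c("rdf-xml", "turtle", "ntriples")

check_format <- function(format) {
  if (!is.character(format) || length(format) != 1L || !(format %in% RDF_FORMATS)) {
    stop(sprintf("format error: unsupported serialization format '%s'",
                 paste(format, collapse = ",")), call. = FALSE)
  }
  format
}

split_iri <- function(iri) {
  # split at the last '#' or '/', namespace part keeps the separator
  pos <- regexpr("[#/][^#/]*$", iri)
  if (pos < 0) return(NULL)
  local <- substr(iri, pos + 1L, nchar(iri))
  if (!grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local)) return(NULL)
  list(ns = substr(iri, 1L, pos), local = local)
}

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  gsub("\"", "&quot;", xml_escape_text(x), fixed = TRUE)
}

# prefix assignment for serialization: declared prefixes first (longest
# namespace wins), generated ns1, ns2, ... for namespaces with no prefix
prefix_table <- function(namespaces, nsmap) {
  out <- character()
  auto <- 0L
  decl <- nsmap$prefixes
  for (ns in namespaces) {
    hit <- names(decl)[!is.na(decl) & decl == ns]
    if (length(hit)) {
      out[[hit[1]]] <- ns
    } else {
      auto <- auto + 1L
      out[[paste0("ns", auto)]] <- ns
    }
  }
  out
}

serialize_rdfxml <- function(graph) {
  df <- canonical_triples(graph)
  nsmap <- graph$nsmap
  # namespaces needed for QNames: all predicates + element types
  pred_ns <- vapply(unique(df$p), function(p) {
    sp <- split_iri(p)
    if (is.null(sp)) stop(sprintf(
      "format error: predicate '%s' cannot be written as an XML QName", p),
      call. = FALSE)
    sp$ns
  }, character(1))
  type_o <- unique(df$o[df$p == RDF_TYPE & !df$o_lit & !is_blank(df$o)])
  type_ns <- character()
  for (t in type_o) {
    sp <- split_iri(t)
    if (!is.null(sp)) type_ns <- c(type_ns, sp$ns)
  }
  namespaces <- sort(unique(c(NS_RDF, pred_ns, type_ns)), method = "radix")
  ptab <- prefix_table(namespaces, nsmap)
  qname <- function(iri) {
    sp <- split_iri(iri)
    if (is.null(sp)) return(NULL)
    pfx <- names(ptab)[ptab == sp$ns]
    if (!length(pfx)) return(NULL)
    paste0(pfx[1], ":", sp$local)
  }
  decls <- vapply(sort(names(ptab), method = "radix"), function(p)
    sprintf("xmlns:%s=\"%s\"", p, xml_escape_attr(ptab[[p]])), character(1))
  base_attr <- if (!is.na(nsmap$base))
    sprintf("\n         xml:base=\"%s\"", xml_escape_attr(nsmap$base)) else ""
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           paste0("<rdf:RDF ", paste(decls, collapse = "\n         "), base_attr, ">"))
  subj_attr <- function(s) {
    if (is_blank(s)) sprintf("rdf:nodeID=\"%s\"", substr(s, 3L, nchar(s)))
    else sprintf("rdf:about=\"%s\"", xml_escape_attr(s))
  }
  for (s in unique(df$s)) {
    rows <- df[df$s == s, , drop = FALSE]
    types <- which(rows$p == RDF_TYPE & !rows$o_lit & !is_blank(rows$o))
    elem <- "rdf:Description"
    if (length(types)) {
      q <- qname(rows$o[types[1]])
      if (!is.null(q)) {
        elem <- q
        rows <- rows[-types[1], , drop = FALSE]
      }
    }
    out <- c(out, sprintf("  <%s %s>", elem, subj_attr(s)))
    for (i in seq_len(nrow(rows))) {
      pq <- qname(rows$p[i])
      if (rows$o_lit[i]) {
        out <- c(out, sprintf("    <%s>%s</%s>", pq,
                              xml_escape_text(rows$o[i]), pq))
      } else if (is_blank(rows$o[i])) {
        out <- c(out, sprintf("    <%s rdf:nodeID=\"%s\"/>", pq,
                              substr(rows$o[i], 3L, nchar(rows$o[i]))))
      } else {
        out <- c(out, sprintf("    <%s rdf:resource=\"%s\"/>", pq,
                              xml_escape_attr(rows$o[i])))
      }
    }
    out <- c(out, sprintf("  </%s>", elem))
  }
  out <- c(out, "</rdf:RDF>", "")
  paste(out, collapse = "\n")
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

ttl_unescape <- function(x) {
  m <- gregexpr("\\\\u[0-9A-Fa-f]{4}|\\\\.|.", x, perl = TRUE)
  toks <- regmatches(x, m)[[1]]
  paste(vapply(toks, function(t) {
    if (startsWith(t, "\\")) {
      switch(substr(t, 2L, 2L),
             "n" = "\n", "r" = "\r", "t" = "\t",
             "\"" = "\"", "\\" = "\\",
             "u" = intToUtf8(strtoi(substr(t, 3L, 6L), 16L)),
             substr(t, 2L, 2L))
    } else t
  }, character(1)), collapse = "")
}

# safe Turtle prefixed-name local part (conservative: no dots)
ttl_local_ok <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_-]*$", x)

serialize_turtle <- function(graph, use_prefixes = TRUE) {
  df <- canonical_triples(graph)
  nsmap <- graph$nsmap
  base <- nsmap$base
  term <- function(x, lit) {
    if (lit) return(paste0("\"", ttl_escape(x), "\""))
    if (is_blank(x)) return(x)
    if (use_prefixes) {
      sp <- split_iri(x)
      if (!is.null(sp) && ttl_local_ok(sp$local)) {
        pfx <- names(nsmap$prefixes)[nsmap$prefixes == sp$ns]
        if (length(pfx)) return(paste0(pfx[1], ":", sp$local))
      }
      if (use_prefixes && !is.na(base) && startsWith(x, paste0(base, "#"))) {
        return(paste0("<", substr(x, nchar(base) + 1L, nchar(x)), ">"))
      }
    }
    paste0("<", x, ">")
  }
  used_pfx <- character()
  lines <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    ts <- term(df$s[i], FALSE)
    tp <- term(df$p[i], FALSE)
    to <- term(df$o[i], df$o_lit[i])
    for (t in c(ts, tp, to)) {
      if (grepl("^[A-Za-z_][A-Za-z0-9_-]*:", t) && !startsWith(t, "_:")) {
        used_pfx <- c(used_pfx, sub(":.*$", "", t))
      }
    }
    lines[i] <- paste0(ts, " ", tp, " ", to, " .")
  }
  header <- character()
  if (use_prefixes) {
    if (!is.na(base)) header <- c(header, sprintf("@base <%s> .", base))
    for (p in sort(unique(used_pfx), method = "radix")) {
      header <- c(header, sprintf("@prefix %s: <%s> .", p, nsmap$prefixes[[p]]))
    }
    if (length(header)) header <- c(header, "")
  }
  paste(c(header, lines, ""), collapse = "\n")
}

serialize_ntriples <- function(graph) serialize_turtle(graph, use_prefixes = FALSE)

#' Serialize a graph
#'
#' Deterministic: the same graph always yields byte-identical output (triples
#' in canonical order, sorted prefix declarations).
#'
#' @param graph A `tma_graph`.
#' @param format One of `"rdf-xml"`, `"turtle"`, `"ntriples"`.
#' @return A single character string (the document).
#' @export
serialize_rdf <- function(graph, format = "rdf-xml") {
  stopifnot(inherits(graph, "tma_graph"))
  switch(check_format(format),
         "rdf-xml" = serialize_rdfxml(graph),
         "turtle" = serialize_turtle(graph),
         "ntriples" = serialize_ntriples(graph))
}

resolve_ref <- function(ref, base) {
  if (is_absolute_iri(ref) || grepl("^urn:", ref)) return(ref)
  if (is.na(base)) {
    if (grepl(SCHEME_RE, ref)) return(ref)
    stop(sprintf("parse error: relative reference '%s' with no base", ref),
         call. = FALSE)
  }
  if (ref == "") return(base)
  if (startsWith(ref, "#")) return(paste0(base, ref))
  if (grepl(SCHEME_RE, ref)) return(ref)
  # minimal relative resolution: replace everything after the last "/"
  sub("/[^/]*$", paste0("/", ref), base)
}

parse_rdfxml <- function(text) {
  doc <- tryCatch(suppressWarnings(xml2::read_xml(text)),
                  error = function(e) stop(sprintf("parse error: %s",
                                                   conditionMessage(e)),
                                           call. = FALSE))
  root <- xml2::xml_root(doc)
  nsobj <- xml2::xml_ns(doc)           # for qualified-name lookup
  nstab <- stats::setNames(as.character(nsobj), names(nsobj))
  base <- xml2::xml_attr(root, "base") # xml:base
  if (is.na(base)) base <- NA_character_
  expand_q <- function(qn) {
    if (grepl(":", qn, fixed = TRUE)) {
      pfx <- sub(":.*$", "", qn)
      ns <- nstab[[pfx]]
      if (is.null(ns) || is.na(ns)) {
        stop(sprintf("parse error: undeclared prefix '%s'", pfx), call. = FALSE)
      }
      paste0(ns, sub("^[^:]*:", "", qn))
    } else {
      stop(sprintf("parse error: unqualified element name '%s'", qn),
         call. = FALSE)
    }
  }
  get_attr <- function(node, local) {
    at <- xml2::xml_attrs(node)
    hit <- names(at)[sub("^.*:", "", names(at)) == local]
    if (length(hit)) at[[hit[1]]] else NA_character_
  }
  acc <- list()
  emit <- function(s, p, o, o_lit) {
    acc[[length(acc) + 1L]] <<- list(s = s, p = p, o = o, o_lit = o_lit)
  }
  bcount <- 0L
  node_subject <- function(node) {
    about <- get_attr(node, "about")
    if (!is.na(about)) return(resolve_ref(about, base))
    id <- get_attr(node, "ID")
    if (!is.na(id)) return(resolve_ref(paste0("#", id), base))
    nid <- get_attr(node, "nodeID")
    if (!is.na(nid)) return(paste0("_:", nid))
    bcount <<- bcount + 1L
    paste0("_:gen", bcount)
  }
  walk_node <- function(node) {
    s <- node_subject(node)
    qn <- xml2::xml_name(node, ns = nsobj)
    full <- expand_q(qn)
    if (full != paste0(NS_RDF, "Description")) emit(s, RDF_TYPE, full, FALSE)
    for (child in xml2::xml_children(node)) {
      p <- expand_q(xml2::xml_name(child, ns = nsobj))
      res <- get_attr(child, "resource")
      nid <- get_attr(child, "nodeID")
      kids <- xml2::xml_children(child)
      if (!is.na(res)) {
        emit(s, p, resolve_ref(res, base), FALSE)
      } else if (!is.na(nid)) {
        emit(s, p, paste0("_:", nid), FALSE)
      } else if (length(kids)) {
        o <- walk_node(kids[[1]])
        emit(s, p, o, FALSE)
      } else {
        emit(s, p, xml2::xml_text(child), TRUE)
      }
    }
    s
  }
  for (node in xml2::xml_children(root)) walk_node(node)
  # xml2 names default namespaces d1, d2, ...; keep declared prefixes only
  prefixes <- nstab[!grepl("^d[0-9]+$", names(nstab)) & names(nstab) != "xml"]
  g <- tma_graph(tma_nsmap(prefixes, base = base))
  if (length(acc)) {
    g <- add_triples(g,
                     vapply(acc, `[[`, character(1), "s"),
                     vapply(acc, `[[`, character(1), "p"),
                     vapply(acc, `[[`, character(1), "o"),
                     vapply(acc, `[[`, logical(1), "o_lit"))
  }
  g
}

TTL_TOKEN_RE <- paste0(
  "@prefix|@base|",
  "<[^>]*>|",
  "\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^<[^>]*>|@[A-Za-z][A-Za-z0-9-]*)?|",
  "_:[A-Za-z0-9_.-]+|",
  "[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.%-]*|",
  "\\ba\\b|",
  "[.;,]|",
  "#[^\n]*"
)

parse_turtle <- function(text) {
  toks <- regmatches(text, gregexpr(TTL_TOKEN_RE, text, perl = TRUE))[[1]]
  toks <- toks[!startsWith(toks, "#")]
  prefixes <- character()
  base <- NA_character_
  g_triples <- list()
  i <- 1L
  n <- length(toks)
  peek <- function() if (i <= n) toks[i] else NA_character_
  take <- function() {
    if (i > n) stop("parse error: unexpected end of Turtle input", call. = FALSE)
    t <- toks[i]; i <<- i + 1L; t
  }
  expect <- function(t) {
    got <- take()
    if (got != t) stop(sprintf("parse error: expected '%s', got '%s'", t, got),
                       call. = FALSE)
  }
  term <- function(tok) {
    if (startsWith(tok, "<")) {
      list(v = resolve_ref(substr(tok, 2L, nchar(tok) - 1L), base), lit = FALSE)
    } else if (startsWith(tok, "\"")) {
      body <- sub("(\\^\\^<[^>]*>|@[A-Za-z][A-Za-z0-9-]*)$", "", tok)
      list(v = ttl_unescape(substr(body, 2L, nchar(body) - 1L)), lit = TRUE)
    } else if (startsWith(tok, "_:")) {
      list(v = tok, lit = FALSE)
    } else if (tok == "a") {
      list(v = RDF_TYPE, lit = FALSE)
    } else if (grepl(":", tok, fixed = TRUE)) {
      pfx <- sub(":.*$", "", tok)
      if (!(pfx %in% names(prefixes))) {
        stop(sprintf("parse error: undeclared prefix '%s'", pfx), call. = FALSE)
      }
      ns <- prefixes[[pfx]]
      list(v = paste0(ns, sub("^[^:]*:", "", tok)), lit = FALSE)
    } else {
      stop(sprintf("parse error: unexpected token '%s'", tok), call. = FALSE)
    }
  }
  while (i <= n) {
    tok <- take()
    if (tok == "@prefix") {
      ptok <- take()
      pfx <- sub(":$", "", sub(":.*$", "", ptok))
      # @prefix token comes through as "pfx:" (empty local)
      iritok <- take()
      prefixes[[pfx]] <- substr(iritok, 2L, nchar(iritok) - 1L)
      expect(".")
    } else if (tok == "@base") {
      iritok <- take()
      base <- substr(iritok, 2L, nchar(iritok) - 1L)
      expect(".")
    } else {
      s <- term(tok)
      if (s$lit) stop("parse error: literal subject", call. = FALSE)
      repeat {
        p <- term(take())
        if (p$lit || is_blank(p$v)) stop("parse error: invalid predicate",
                                         call. = FALSE)
        repeat {
          o <- term(take())
          g_triples[[length(g_triples) + 1L]] <-
            list(s = s$v, p = p$v, o = o$v, o_lit = o$lit)
          if (identical(peek(), ",")) { take() } else break
        }
        if (identical(peek(), ";")) { take() } else break
      }
      expect(".")
    }
  }
  g <- tma_graph(tma_nsmap(prefixes, base = base))
  if (length(g_triples)) {
    g <- add_triples(g,
                     vapply(g_triples, `[[`, character(1), "s"),
                     vapply(g_triples, `[[`, character(1), "p"),
                     vapply(g_triples, `[[`, character(1), "o"),
                     vapply(g_triples, `[[`, logical(1), "o_lit"))
  }
  g
}

#' Parse an RDF document
#'
#' Shorthands (QNames, prefixed names, relative references) are expanded to
#' absolute IRIs; the document base (`xml:base` / `@base`) is honored. The
#' returned graph carries the namespace map declared by the document.
#'
#' @param text Document content: a character scalar or raw vector.
#' @param format One of `"rdf-xml"`, `"turtle"`, `"ntriples"`.
#' @return A `tma_graph`.
#' @export
parse_rdf <- function(text, format = "rdf-xml") {
  if (is.raw(text)) text <- rawToChar(text)
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  switch(check_format(format),
         "rdf-xml" = parse_rdfxml(text),
         "turtle" = parse_turtle(text),
         "ntriples" = parse_turtle(text))
}

format_from_path <- function(path) {
  ext <- tolower(sub("^.*\\.", "", path))
  switch(ext,
         "owl" = , "rdf" = , "xml" = "rdf-xml",
         "ttl" = "turtle",
         "nt" = "ntriples",
         "rdf-xml")
}

#' Read an RDF file
#' @param path File path (`.owl`/`.rdf` RDF/XML, `.ttl` Turtle, `.nt` N-Triples).
#' @param format Serialization format; guessed from the extension by default.
#' @return A `tma_graph`.
#' @export
read_rdf <- function(path, format = format_from_path(path)) {
  parse_rdf(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n"), format)
}

#' Write an RDF file
#' @param graph A `tma_graph`.
#' @param path Output path.
#' @inheritParams read_rdf
#' @return `path`, invisibly.
#' @export
write_rdf <- function(graph, path, format = format_from_path(path)) {
  writeLines(serialize_rdf(graph, format), path, useBytes = TRUE)
  invisible(path)
}
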