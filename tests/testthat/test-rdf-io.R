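test_that("parse produces fully expanded triples from the example document", {
  g <- example_graph()
  doc <- serialize_rdf(g, "rdf-xml")
  g2 <- parse_rdf(doc, "rdf-xml")
  df <- g2$triples
  hit <- df[df$p == paste0(TMA_NS, "drill_site"), ]
  expect_equal(hit$s, paste0(EXAMPLE_BASE, "#coreD4"))
  expect_equal(hit$o, "78,90")
  expect_true(hit$o_lit)
  expect_equal(g2$nsmap$base, EXAMPLE_BASE)
})

test_that("serialization is deterministic and declares only used prefixes", {
  g <- example_graph()
  for (fmt in c("rdf-xml", "turtle", "ntriples")) {
    expect_identical(serialize_rdf(g, fmt), serialize_rdf(g, fmt))
  }
  ttl <- serialize_rdf(g, "turtle")
  expect_true(grepl("@prefix tma:", ttl))
  expect_true(grepl("@prefix dc:", ttl))
  expect_false(grepl("@prefix owl:", ttl))  # owl unused by instance data
  expect_error(serialize_rdf(g, "json-ld"), "format error")
})

test_that("duplicate statements collapse and literals survive verbatim", {
  g <- tma_graph(example_nsmap())
  g <- add_triples(g, "http://x.org/a", paste0(TMA_NS, "drill_site"),
                   "78,90", TRUE)
  g <- add_triples(g, "http://x.org/a", paste0(TMA_NS, "drill_site"),
                   "78,90", TRUE)
  expect_equal(graph_size(g), 1L)
  for (fmt in c("rdf-xml", "turtle", "ntriples")) {
    g2 <- parse_rdf(serialize_rdf(g, fmt), fmt)
    expect_equal(g2$triples$o, "78,90", info = fmt)
  }
  # awkward literal content
  g3 <- tma_graph(example_nsmap())
  lits <- c("a \"quoted\" value", "tab\there", "line\nbreak",
            "<xml> & entities", "trailing space ")
  g3 <- add_triples(g3, "http://x.org/a", paste0(TMA_NS, "result"), lits, TRUE)
  for (fmt in c("rdf-xml", "turtle", "ntriples")) {
    g4 <- parse_rdf(serialize_rdf(g3, fmt), fmt)
    expect_setequal(g4$triples$o, lits)
  }
})

test_that("parse/serialize round-trips are isomorphisms across seeds", {
  for (seed in 1:6) {
    m <- generate_model(small_spec(seed))
    g <- to_graph(m)
    for (fmt in c("rdf-xml", "turtle", "ntriples")) {
      g2 <- parse_rdf(serialize_rdf(g, fmt), fmt)
      expect_true(graph_isomorphic(g, g2), info = paste(seed, fmt))
    }
  }
})

test_that("canonical order starts at the array resource and ignores input order", {
  g <- example_graph()
  df <- canonical_triples(g)
  expect_true(endsWith(df$s[1], "block/RP2008-325") ||
                endsWith(df$s[1], "tma/000001"))
  # permuted insertion gives the same canonical order
  perm <- sample(seq_len(nrow(g$triples)))
  g2 <- tma_graph(g$nsmap)
  g2 <- add_triples(g2, g$triples$s[perm], g$triples$p[perm],
                    g$triples$o[perm], g$triples$o_lit[perm])
  expect_identical(canonical_triples(g2), df)
  # singleton
  g3 <- tma_graph()
  g3 <- add_triples(g3, "http://x.org/a", RDF_TYPE_IRI, paste0(TMA_NS, "tma"))
  expect_equal(nrow(canonical_triples(g3)), 1L)
})

test_that("isomorphism respects blank-node bijections", {
  mk <- function(b1, b2) {
    g <- tma_graph(example_nsmap())
    g <- add_triples(g, "http://x.org/core1", paste0(TMA_NS, "clinical_annotation"), b1)
    g <- add_triples(g, b1, paste0(TMA_NS, "status"), "ok", TRUE)
    g <- add_triples(g, "http://x.org/core2", paste0(TMA_NS, "clinical_annotation"), b2)
    g <- add_triples(g, b2, paste0(TMA_NS, "status"), "depleted", TRUE)
    g
  }
  g <- mk("_:a", "_:b")
  expect_true(graph_isomorphic(g, g))
  expect_true(graph_isomorphic(g, mk("_:x", "_:y")))
  # swapped blank roles still isomorphic via the crossed bijection
  expect_true(graph_isomorphic(g, mk("_:y", "_:x")))
  # literal difference breaks isomorphism
  g2 <- mk("_:a", "_:b")
  g2$triples$o[g2$triples$o == "ok"] <- "damaged"
  expect_false(graph_isomorphic(g, g2))
  # blank-node round trip through every format
  for (fmt in c("rdf-xml", "turtle", "ntriples")) {
    expect_true(graph_isomorphic(g, parse_rdf(serialize_rdf(g, fmt), fmt)),
                info = fmt)
  }
})

test_that("malformed documents and unknown prefixes raise parse errors", {
  expect_error(parse_rdf("<rdf:RDF", "rdf-xml"), "parse error")
  expect_error(parse_rdf("foo:bar foo:baz foo:qux .", "turtle"),
               "undeclared prefix")
  expect_error(parse_rdf("<http://x.org/a> <http://x.org/p>", "ntriples"),
               "parse error")
  # empty documents parse to empty graphs
  empty <- "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"/>"
  expect_equal(graph_size(parse_rdf(empty, "rdf-xml")), 0L)
  expect_equal(graph_size(parse_rdf("", "turtle")), 0L)
})

test_that("our RDF/XML output is read identically by an independent parser", {
  py <- Sys.which("python")
  m <- generate_model(small_spec(4))
  g <- to_graph(m)
  xml_path <- tempfile(fileext = ".owl")
  nt_path <- tempfile(fileext = ".nt")
  write_rdf(g, xml_path, "rdf-xml")
  write_rdf(g, nt_path, "ntriples")
  script <- paste(
    "import sys, rdflib",
    "g1 = rdflib.Graph(); g1.parse(sys.argv[1], format='xml')",
    "g2 = rdflib.Graph(); g2.parse(sys.argv[2], format='nt')",
    "print(len(g1), set(g1) == set(g2))",
    sep = "\n")
  out <- system2(py, c("-c", shQuote(script), xml_path, nt_path),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(out[length(out)], paste(graph_size(g), "True"))
})
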