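test_that("vocabulary has the published cardinalities and hierarchy", {
  v <- build_schema()
  expect_equal(nrow(v$classes), 7L)
  expect_equal(sum(v$properties$kind == "object"), 10L)
  expect_equal(sum(v$properties$kind == "annotation"), 15L)
  expect_setequal(v$classes$local_name[v$classes$abstract],
                  c("repository_product", "experimental_component"))
  # every concrete class hangs off an abstract parent
  concrete <- v$classes[!v$classes$abstract, ]
  expect_true(all(concrete$parent %in%
                    v$classes$local_name[v$classes$abstract]))
  expect_true("core_on_slide" %in% v$classes$local_name)
  expect_equal(v$namespace, TMA_NS)
})

test_that("inverse pairing is exactly the four hierarchy pairs, symmetric", {
  v <- build_schema()
  pairs <- list(c("includes_block", "included_in_tma"),
                c("includes_slide", "cut_from_block"),
                c("block_includes_core", "included_in_block"),
                c("slide_includes_core", "affixed_to_slide"))
  for (pr in pairs) {
    expect_equal(inverse_of(v, pr[1]), pr[2])
    expect_equal(inverse_of(v, pr[2]), pr[1])
    expect_equal(inverse_of(v, inverse_of(v, pr[1])), pr[1])
  }
  expect_true(is.na(inverse_of(v, "derived_from_core")))
  expect_true(is.na(inverse_of(v, "donor_block")))
  paired <- v$properties[!is.na(v$properties$inverse), ]
  expect_equal(nrow(paired), 8L)
  expect_error(inverse_of(v, "no_such_property"), "lookup error")
})

test_that("paired properties have dual domain/range and a direction each", {
  v <- build_schema()
  pr <- v$properties
  for (i in which(!is.na(pr$inverse))) {
    q <- pr[pr$local_name == pr$inverse[i], ]
    expect_equal(pr$domain[i], q$range)
    expect_equal(pr$range[i], q$domain)
    expect_true(pr$direction[i] %in% c("top_down", "bottom_up"))
    expect_false(pr$direction[i] == q$direction)
  }
  expect_equal(pr$domain[pr$local_name == "includes_block"], "tma")
  expect_equal(pr$range[pr$local_name == "donor_block"], "external")
  expect_equal(pr$domain[pr$local_name == "derived_from_core"], "core_on_slide")
  top_down <- pr$local_name[pr$direction == "top_down"]
  expect_setequal(top_down, c("includes_block", "includes_slide",
                              "block_includes_core", "slide_includes_core"))
})

test_that("emitted schema document round-trips and carries the axioms", {
  v <- build_schema()
  for (fmt in c("rdf-xml", "turtle")) {
    doc <- emit_schema_document(v, fmt)
    expect_true(vocab_equal(parse_schema_document(doc, fmt), v))
  }
  g <- parse_rdf(emit_schema_document(v), "rdf-xml")
  df <- g$triples
  owl_class <- "http://www.w3.org/2002/07/owl#Class"
  expect_equal(sum(df$p == RDF_TYPE_IRI & df$o == owl_class), 7L)
  inv <- df[df$p == "http://www.w3.org/2002/07/owl#inverseOf", ]
  expect_true(paste0(TMA_NS, "includes_block") %in% inv$s)
  expect_true(paste0(TMA_NS, "included_in_tma") %in%
                inv$o[inv$s == paste0(TMA_NS, "includes_block")])
  expect_equal(sum(df$p == RDF_TYPE_IRI &
                     df$o == "http://www.w3.org/2002/07/owl#ObjectProperty"),
               10L)
  expect_equal(sum(df$p == RDF_TYPE_IRI &
                     df$o == "http://www.w3.org/2002/07/owl#AnnotationProperty"),
               15L)
  expect_error(emit_schema_document(v, "json-ld"), "format error")
})

test_that("parent assignment is configurable", {
  v <- build_schema(parent_map = c(tma = "repository_product",
                                   block = "repository_product",
                                   slide = "experimental_component",
                                   core_in_block = "experimental_component",
                                   core_on_slide = "experimental_component"))
  expect_equal(v$classes$parent[v$classes$local_name == "slide"],
               "experimental_component")
  expect_error(build_schema(parent_map = c(tma = "block")), "parent_map")
})
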