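test_that("the worked example validates with zero errors", {
  rep <- validate(example_graph())
  expect_true(rep$valid)
  expect_equal(sum(rep$findings$severity == "error"), 0L)
  # external references are informational only
  expect_true("W5" %in% rep$findings$rule_id)
})

test_that("constructed violations trigger the matching rules", {
  base <- example_graph()
  ns <- TMA_NS
  tma <- "http://www.institutionXYZ.org/tma/000001"
  # E2: hierarchy property used from the wrong end
  g <- add_triples(base, tma, paste0(ns, "slide_includes_core"),
                   paste0(EXAMPLE_BASE, "#coreD4"))
  rep <- validate(g)
  expect_false(rep$valid)
  expect_true("E2" %in% rep$findings$rule_id)
  # E4: dangling internal fragment
  g <- add_triples(base, paste0(EXAMPLE_BASE, "#slide058"),
                   paste0(ns, "slide_includes_core"),
                   paste0(EXAMPLE_BASE, "#coreZ9"))
  rep <- validate(g)
  expect_true("E4" %in% rep$findings$rule_id)
  # E1: untyped subject of an object property
  g <- add_triples(base, "http://elsewhere.org/mystery",
                   paste0(ns, "includes_slide"),
                   paste0(EXAMPLE_BASE, "#slide058"))
  expect_true("E1" %in% validate(g)$findings$rule_id)
  # E5: abstract typing
  g <- add_triples(base, paste0(EXAMPLE_BASE, "#thing"), RDF_TYPE_IRI,
                   paste0(ns, "repository_product"))
  expect_true("E5" %in% validate(g)$findings$rule_id)
  # E3: internal typed object of the wrong class
  g <- add_triples(base, paste0(EXAMPLE_BASE, "#slide058"),
                   paste0(ns, "slide_includes_core"),
                   paste0(EXAMPLE_BASE, "#coreD4"))
  g <- add_triples(g, paste0(EXAMPLE_BASE, "#slide058"), RDF_TYPE_IRI,
                   paste0(ns, "slide"))
  expect_true("E3" %in% validate(g)$findings$rule_id)
})

test_that("stylistic findings are warnings, not errors", {
  g <- example_graph()
  g <- add_triples(g, paste0(EXAMPLE_BASE, "#slide058-D4"),
                   paste0(TMA_NS, "location"), "not-a-grid-ref", TRUE)
  g <- add_triples(g, paste0(EXAMPLE_BASE, "#coreD4"),
                   paste0(TMA_NS, "drill_site"), "somewhere", TRUE)
  g <- add_triples(g, paste0(EXAMPLE_BASE, "#coreD4"),
                   paste0(TMA_NS, "diagnosis"), "prostate cancer", TRUE)
  rep <- validate(g)
  expect_true(rep$valid)
  expect_true(all(c("W2", "W3", "W4") %in% rep$findings$rule_id))
})

test_that("validate does not mutate its input", {
  g <- example_graph()
  before <- canonical_triples(g)
  invisible(validate(g))
  expect_identical(canonical_triples(g), before)
})

test_that("inverse materialization adds exactly the paired statements", {
  g <- tma_graph(example_nsmap())
  blk <- "http://x.org/block/1"
  slide <- paste0(EXAMPLE_BASE, "#slide058")
  g <- add_triples(g, blk, paste0(TMA_NS, "includes_slide"), slide)
  gm <- materialize_inverses(g)
  expect_equal(graph_size(gm), 2L)
  df <- gm$triples
  expect_true(any(df$s == slide & df$p == paste0(TMA_NS, "cut_from_block") &
                    df$o == blk))
  # empty graph fixed point
  expect_equal(graph_size(materialize_inverses(tma_graph())), 0L)
})

test_that("materialization is idempotent and symmetric on synthetic graphs", {
  v <- build_schema()
  pairs <- v$properties[v$properties$kind == "object" &
                          !is.na(v$properties$inverse), ]
  for (seed in c(2, 5)) {
    g <- to_graph(generate_model(small_spec(seed)))
    gm <- materialize_inverses(g, v)
    expect_identical(canonical_triples(materialize_inverses(gm, v)),
                     canonical_triples(gm))
    df <- gm$triples
    tok <- sub(TMA_NS, "", df$p, fixed = TRUE)
    keys <- paste(df$s, df$p, df$o)
    for (i in which(tok %in% pairs$local_name)) {
      q <- pairs$inverse[pairs$local_name == tok[i]]
      expect_true(paste(df$o[i], paste0(TMA_NS, q), df$s[i]) %in% keys)
    }
  }
})

test_that("stripping keeps one direction and materialization restores it", {
  g <- to_graph(generate_model(small_spec(3)))
  gm <- materialize_inverses(g)
  for (keep in c("top_down", "bottom_up")) {
    gs <- strip_inverses(gm, keep = keep)
    tok <- sub(TMA_NS, "", gs$triples$p, fixed = TRUE)
    v <- build_schema()
    banned <- v$properties$local_name[v$properties$direction ==
                                        setdiff(c("top_down", "bottom_up"), keep)]
    expect_false(any(tok %in% banned))
    expect_identical(canonical_triples(materialize_inverses(gs)),
                     canonical_triples(gm))
  }
  # unpaired properties pass through untouched
  g2 <- tma_graph(example_nsmap())
  g2 <- add_triples(g2, paste0(EXAMPLE_BASE, "#slide058-D4"),
                    paste0(TMA_NS, "derived_from_core"),
                    paste0(EXAMPLE_BASE, "#coreD4"))
  expect_identical(canonical_triples(strip_inverses(g2, keep = "top_down")),
                   canonical_triples(g2))
  # unmaterialized paired input is rejected
  g3 <- tma_graph(example_nsmap())
  g3 <- add_triples(g3, "http://x.org/block/1",
                    paste0(TMA_NS, "includes_slide"),
                    paste0(EXAMPLE_BASE, "#slide058"))
  expect_error(strip_inverses(g3, keep = "bottom_up"), "not inverse-materialized")
})
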