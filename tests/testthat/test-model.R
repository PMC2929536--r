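test_that("node insertion enforces class and uniqueness rules", {
  m <- tma_model(nsmap = example_nsmap())
  m <- add_node(m, "tma", "http://www.institutionXYZ.org/tma/000001",
                annotations = list("dc:title" = "All-Purpose Tissue Array"))
  node <- m$nodes[["http://www.institutionXYZ.org/tma/000001"]]
  expect_equal(length(node$annotations), 1L)
  expect_equal(unclass(node$annotations[[paste0(DC_NS, "title")]][[1]]),
               "All-Purpose Tissue Array")
  expect_error(add_node(m, "repository_product", "http://x.org/r1"),
               "abstract")
  expect_error(add_node(m, "tma", "http://www.institutionXYZ.org/tma/000001"),
               "duplicate")
  expect_error(add_node(m, "banana", "http://x.org/b"), "unknown class")
})

test_that("edge insertion checks domain always and range for internal nodes", {
  m <- tma_model(nsmap = example_nsmap())
  m <- add_node(m, "tma", "http://x.org/tma/1")
  m <- add_node(m, "block", "http://x.org/block/1")
  m <- add_node(m, "slide", "#slide058")
  m <- add_edge(m, "http://x.org/block/1", "includes_slide", "#slide058")
  expect_equal(nrow(m$edges), 1L)
  # duplicates collapse
  m <- add_edge(m, "http://x.org/block/1", "includes_slide", "#slide058")
  expect_equal(nrow(m$edges), 1L)
  expect_error(add_edge(m, "http://x.org/tma/1", "slide_includes_core",
                        "#slide058"), "domain violation")
  expect_error(add_edge(m, "http://x.org/block/1", "includes_slide",
                        "http://x.org/tma/1"), "range violation")
  # external object accepted even for class-ranged properties
  m2 <- add_node(m, "core_in_block", "#coreD4")
  m2 <- add_edge(m2, "#coreD4", "donor_block",
                 "http://www.institutionXYZ.org/block/RP2007-228")
  expect_equal(nrow(m2$edges), 2L)
  expect_error(add_edge(m, "http://x.org/block/1", "location", "#slide058"),
               "not an object property")
  expect_error(add_edge(m, "http://x.org/absent", "includes_slide",
                        "#slide058"), "not in model")
})

test_that("the worked example projects to exactly its 18 published triples", {
  g <- example_graph()
  got <- canonical_triples(g)
  want <- example_triples()
  expect_equal(nrow(got), 18L)
  expect_identical(triple_strings(got), triple_strings(want))
})

test_that("triple count decomposes into nodes + annotations + edges", {
  m <- generate_model(small_spec(9))
  g <- to_graph(m)
  n_ann <- sum(vapply(m$nodes, function(n)
    sum(lengths(n$annotations)), integer(1)))
  expect_equal(graph_size(g), length(m$nodes) + n_ann + nrow(m$edges))
})

test_that("from_graph(to_graph(m)) is the identity on synthetic models", {
  for (seed in c(1, 7, 23)) {
    m <- generate_model(small_spec(seed))
    expect_true(model_equal(m, from_graph(to_graph(m))), info = seed)
  }
})

test_that("from_graph types the worked example and keeps the term node", {
  g <- example_graph()
  m <- from_graph(g)
  expect_equal(unname(node_counts(m)), c(1L, 1L, 1L, 1L, 1L))
  # the diagnosis term typing survives as a verbatim extra triple
  expect_equal(nrow(m$extra), 1L)
  expect_equal(m$extra$o, NCI_PROSTATE)
  expect_true(graph_isomorphic(to_graph(m), g))
})

test_that("owl:Class typing predicates are accepted and normalized", {
  g <- tma_graph(example_nsmap())
  g <- add_triples(g, "http://x.org/tma/1",
                   "http://www.w3.org/2002/07/owl#Class",
                   paste0(TMA_NS, "tma"))
  rep <- validate(g)
  expect_true(rep$valid)
  expect_true("W1" %in% rep$findings$rule_id)
  m <- from_graph(g)
  expect_equal(unname(node_counts(m)["tma"]), 1L)
})

test_that("empty structures round-trip as empty", {
  m <- tma_model(nsmap = example_nsmap())
  g <- to_graph(m)
  expect_equal(graph_size(g), 0L)
  expect_true(model_equal(m, from_graph(g)))
})
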