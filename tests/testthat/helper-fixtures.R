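# Shared fixtures: the published worked example (one TMA, one block, one
# slide, one core in each sense, a diagnosis term node) and small synthetic
# specs used across test files.

EXAMPLE_BASE <- "http://www.the_url_here.org/tma_example1.rdf"
TMA_NS <- "http://bioontology.org/ontologies/tma-minimal#"
DC_NS <- "http://purl.org/dc/elements/1.1#"
RDF_TYPE_IRI <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
NCI_PROSTATE <- "http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#Prostate_Carcinoma"

example_nsmap <- function() default_nsmap(base = EXAMPLE_BASE)
example_policy <- function() uri_policy("www.institutionXYZ.org")

# the worked example built through the model API + term linkage
example_graph <- function() {
  pol <- example_policy()
  tma <- mint_uri(pol, "tma", "000001")
  blk <- mint_uri(pol, "block", "RP2008-325")
  donor <- mint_uri(pol, "block", "RP2007-228")
  m <- tma_model(nsmap = example_nsmap())
  m <- add_node(m, "tma", tma, annotations = list(
    "dc:title" = "All-Purpose Tissue Array",
    "dc:creator" = "Michael J. Becich"))
  m <- add_node(m, "block", blk)
  m <- add_node(m, "slide", "#slide058")
  m <- add_node(m, "core_in_block", "#coreD4", annotations = list(
    repository = "Generic Tissue Bank", drill_site = "78,90"))
  m <- add_node(m, "core_on_slide", "#slide058-D4",
                annotations = list(location = "D4"))
  m <- add_edge(m, tma, "includes_block", blk)
  m <- add_edge(m, blk, "includes_slide", "#slide058")
  m <- add_edge(m, blk, "block_includes_core", "#coreD4")
  m <- add_edge(m, "#slide058", "slide_includes_core", "#slide058-D4")
  m <- add_edge(m, "#coreD4", "donor_block", donor)
  m <- add_edge(m, "#slide058-D4", "derived_from_core", "#coreD4")
  g <- to_graph(m)
  link_term(g, "#coreD4", "diagnosis", NCI_PROSTATE, "#diagnosis1")
}

# the 18 expected statements, frozen with absolute IRIs and exact literals
example_triples <- function() {
  tma <- "http://www.institutionXYZ.org/tma/000001"
  blk <- "http://www.institutionXYZ.org/block/RP2008-325"
  donor <- "http://www.institutionXYZ.org/block/RP2007-228"
  slide <- paste0(EXAMPLE_BASE, "#slide058")
  core <- paste0(EXAMPLE_BASE, "#coreD4")
  sc <- paste0(EXAMPLE_BASE, "#slide058-D4")
  dg <- paste0(EXAMPLE_BASE, "#diagnosis1")
  t <- function(s, p, o, lit = FALSE) data.frame(s = s, p = p, o = o,
                                                 o_lit = lit,
                                                 stringsAsFactors = FALSE)
  df <- rbind(
    t(tma, RDF_TYPE_IRI, paste0(TMA_NS, "tma")),
    t(tma, paste0(DC_NS, "title"), "All-Purpose Tissue Array", TRUE),
    t(tma, paste0(DC_NS, "creator"), "Michael J. Becich", TRUE),
    t(tma, paste0(TMA_NS, "includes_block"), blk),
    t(blk, RDF_TYPE_IRI, paste0(TMA_NS, "block")),
    t(blk, paste0(TMA_NS, "includes_slide"), slide),
    t(blk, paste0(TMA_NS, "block_includes_core"), core),
    t(slide, RDF_TYPE_IRI, paste0(TMA_NS, "slide")),
    t(slide, paste0(TMA_NS, "slide_includes_core"), sc),
    t(core, RDF_TYPE_IRI, paste0(TMA_NS, "core_in_block")),
    t(core, paste0(TMA_NS, "donor_block"), donor),
    t(core, paste0(TMA_NS, "repository"), "Generic Tissue Bank", TRUE),
    t(core, paste0(TMA_NS, "drill_site"), "78,90", TRUE),
    t(core, paste0(TMA_NS, "diagnosis"), dg),
    t(dg, RDF_TYPE_IRI, NCI_PROSTATE),
    t(sc, RDF_TYPE_IRI, paste0(TMA_NS, "core_on_slide")),
    t(sc, paste0(TMA_NS, "location"), "D4", TRUE),
    t(sc, paste0(TMA_NS, "derived_from_core"), core))
  df[order(df$s, df$p, df$o_lit, df$o, method = "radix"), , drop = FALSE]
}

triple_strings <- function(df) {
  sort(paste(df$s, df$p, df$o, df$o_lit, sep = "\r"), method = "radix")
}

small_spec <- function(seed, ...) {
  synth_spec(seed = seed, n_blocks = 2, grid_rows = 3, grid_cols = 4,
             slides_per_block = 1, fill_rate = 0.5, ...)
}
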