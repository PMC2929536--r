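# tmaowl — tissue-microarray provenance as OWL/RDF Linked Data

Tissue microarrays (TMAs) pack hundreds of cylindrical tissue cores into a
single paraffin block that is sectioned into near-identical glass slides and
dispensed to many laboratories over many years. The data describing one TMA —
which donor block each core was drilled from, which slide carries which core
section at which grid address, which diagnosis and which assay results attach
to each section — therefore outlives any one institution's database, and
sharing it requires identifiers and vocabulary that are global in scope.
`tmaowl` is an R toolkit for pathology-informatics and biobanking groups that
want to publish or consume TMA data in that form.

The package represents every statement as an RDF triple
*(subject, predicate, object)* and ships a minimal OWL vocabulary for the TMA
hierarchy:

* **Classes** — two abstract parents (`repository_product`,
  `experimental_component`) over five concrete classes: `tma`, `block`,
  `slide`, `core_in_block` (a core drilled into the array block) and
  `core_on_slide` (the section of that core on one slide).
* **Object properties** — four inverse pairs spanning the hierarchy
  (`includes_block`/`included_in_tma`, `includes_slide`/`cut_from_block`,
  `block_includes_core`/`included_in_block`,
  `slide_includes_core`/`affixed_to_slide`) declared as `owl:inverseOf`
  axioms, plus `derived_from_core` and `donor_block`. The "top-down"
  direction serves whole-hierarchy documents; the "bottom-up" direction lets
  a resource point at a parent catalogued in a different document.
* **Annotation properties** — fifteen open-valued descriptors (`location`,
  `drill_site`, `diagnosis`, `repository`, `result`, ...) that accept either
  literal values (`"78,90"`, `"D4"`) or resource references (an NCI Thesaurus
  diagnosis term, an MGED-described microarray experiment). External IRIs are
  carried opaquely and never fetched.

Identifiers follow the Linked Data rules: mint URIs in an HTTP namespace you
control, keep them stable, and build them from domain-meaningful keys —
`mint_uri(uri_policy("www.institutionXYZ.org"), c("tma", "rdf"), "123456")`
yields `http://www.institutionXYZ.org/tma/rdf/123456`.

Around the vocabulary sit a typed model API, RDF/XML–Turtle–N-Triples
read/write with deterministic canonical output and blank-node-aware graph
isomorphism, a rule-based validator with inverse-property materialization, a
converter from a well-defined TMA XML dialect to OWL instance documents, a
seeded synthetic-fixture generator with rule-targeted mutations, and a
`tma-owl` command-line interface (`inst/cli/tma-owl`).

## Worked example

Build the canonical single-core document through the model API, attach a
diagnosis term, and validate:

```r
library(tmaowl)

ns  <- default_nsmap(base = "http://www.the_url_here.org/tma_example1.rdf")
pol <- uri_policy("www.institutionXYZ.org")

m <- tma_model(nsmap = ns)
m <- add_node(m, "tma", mint_uri(pol, "tma", "000001"),
              annotations = list("dc:title" = "All-Purpose Tissue Array"))
m <- add_node(m, "block", mint_uri(pol, "block", "RP2008-325"))
m <- add_node(m, "slide", "#slide058")
m <- add_node(m, "core_in_block", "#coreD4",
              annotations = list(drill_site = "78,90"))
m <- add_node(m, "core_on_slide", "#slide058-D4",
              annotations = list(location = "D4"))
m <- add_edge(m, mint_uri(pol, "tma", "000001"), "includes_block",
              mint_uri(pol, "block", "RP2008-325"))
m <- add_edge(m, mint_uri(pol, "block", "RP2008-325"), "includes_slide",
              "#slide058")
m <- add_edge(m, mint_uri(pol, "block", "RP2008-325"), "block_includes_core",
              "#coreD4")
m <- add_edge(m, "#slide058", "slide_includes_core", "#slide058-D4")
m <- add_edge(m, "#slide058-D4", "derived_from_core", "#coreD4")
m
#> <tma_model>
#>   tma: 1
#>   block: 1
#>   slide: 1
#>   core_in_block: 1
#>   core_on_slide: 1
#>   edges: 5

g <- to_graph(m)
g <- link_term(g, "#coreD4", "diagnosis",
  "http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#Prostate_Carcinoma")
g
#> <tma_graph> 15 triple(s)

validate(g)
#> <tma_validation_report> valid: TRUE (0 error(s), 1 warning(s))
#>   [W5/warning] http://www.institutionXYZ.org/block/RP2008-325:
#>     external reference via 'includes_block' (target simulated, not fetched)
```

The 15 triples are the five typing statements, three annotations, five
hierarchy edges, and the two statements added by `link_term()` (the
`diagnosis` edge plus the term node's `rdf:type`). The one warning is
informational: block URIs deliberately simulate data files held at another
address. `serialize_rdf(g, "turtle")` (or `"rdf-xml"`, `"ntriples"`) writes
the document; `parse_rdf()` reads it back isomorphically, and
`materialize_inverses(g)` adds the paired bottom-up statements
(`cut_from_block`, `affixed_to_slide`, ...) for consumers that navigate
upward.

The same document can be produced from a well-defined XML file
(`convert_tma_xml()`, dialect XSD in `inst/extdata/tma-xml.xsd`), mirroring
the extract → structure → transform pipeline used to publish repository
holdings.

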