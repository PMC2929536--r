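---
title: "The TMA OWL vocabulary and how tmaowl implements it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The TMA OWL vocabulary and how tmaowl implements it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmaowl)
```

## The data model and its assumptions

A tissue microarray (TMA) is a paraffin block holding hundreds of tissue
cores at grid positions; sectioning the block yields near-identical slides,
each carrying a section of every core. `tmaowl` models exactly this
provenance chain and nothing else: one `tma` contains `block`s, a block is
sectioned into `slide`s and drilled with `core_in_block`s, a slide carries
`core_on_slide`s, and each core-on-slide derives from a core-in-block.
Clinical data, assay semantics and anatomy are deliberately out of scope —
they belong to external ontologies (NCI Thesaurus, MGED, Dublin Core), and
the vocabulary only provides attachment points for references to them.

Three assumptions shape the design:

1. **Statements are triples.** Everything is *(subject, predicate, object)*;
   subjects and predicates are absolute IRIs (or document-scoped blank ids),
   objects are IRIs, blank ids, or plain string literals. Literals carry no
   datatypes: values such as `"78,90"` are opaque tokens whose conventions
   are checked, not enforced.
2. **References cross documents.** A document describing one TMA refers to
   donor blocks, parent arrays, diagnosis terms and experiments that live at
   other addresses. Those IRIs *simulate* the existence of data there; the
   package never dereferences anything. Consequently the validator treats
   external references as informational (`W5`), never as errors.
3. **Hierarchy edges come in inverse pairs.** `includes_slide` and
   `cut_from_block` describe the same fact from opposite ends. OWL lets the
   two be declared inverses of one another, so a document may carry either
   direction and a consumer can materialize the other
   (`materialize_inverses()`); whole-hierarchy documents conventionally use
   the top-down direction (`strip_inverses(keep = "top_down")`).

## The vocabulary

`build_schema()` returns 7 classes, 10 object properties and 15 annotation
properties in the `http://bioontology.org/ontologies/tma-minimal#` namespace.

```{r}
v <- build_schema()
v$classes
subset(v$properties, kind == "object")
```

Two design points here were genuinely open and are worth recording:

* **Abstract parents.** `repository_product` and `experimental_component`
  are abstract (instances may not be typed with them — rule `E5`), but the
  assignment of concrete classes to parents is not fixed by the vocabulary's
  published description. We place `tma`, `block` and `slide` under
  `repository_product` — they are the dispensable physical artifacts a
  repository stocks and ships — and the two core classes under
  `experimental_component`, since cores are the experimental units. The
  assignment is data, and `build_schema(parent_map = ...)` overrides it.
* **"Datatype" properties are annotation-style.** The fifteen descriptor
  properties are used in practice with both value shapes: `repository` takes
  a string, while `diagnosis` points at a term resource and
  `clinical_annotation` at a separate resource or a blank node bundling
  property/value pairs. We therefore model all fifteen with range
  "literal-or-resource" and never reject either shape; the validator only
  warns (`W4`) when usage departs from the observed conventions
  (literal `repository`/`location`/`drill_site`, resource
  `diagnosis`/`clinical_annotation`).
* **Pair direction is derived, not stored.** A paired property is "top-down"
  when its domain ranks above its range in the hierarchy
  (tma < block < slide < cores). This keeps the emitted schema document free
  of non-standard annotations while letting `parse_schema_document()`
  rebuild a vocabulary equal to `build_schema()`.

## Identifiers

Minting follows the Linked Data rules: a `uri_policy()` fixes the scheme and
authority (an HTTP namespace under the publisher's control) and per-class
collection paths; `mint_uri()` appends a percent-encoded, domain-meaningful
key (an accession number, not a database row id). Minting is a pure
function, so identifiers are stable by construction. The encoder keeps the
RFC 3986 unreserved set, uses uppercase hex for everything else, and passes
an existing `%hh` triplet through so already-encoded keys are not
double-encoded.

Shorthand handling mirrors the conventions of the instance documents:
`#fragment` joins the document base with `#`, `prefix:local` concatenates
the prefix's namespace string verbatim, and absolute IRIs pass through.
One inherited quirk: the default `dc` namespace ends in `#`
(`http://purl.org/dc/elements/1.1#`), which is the expansion the shorthand
table of the schema's documentation prescribes even though Dublin Core's
canonical namespace ends in `/`. Namespace strings are configuration, so a
deployment can rebind `dc` to the slash form; the package default follows
the documented expansion.

## Validation rules

`validate()` applies a fixed registry; structural violations are errors,
usage conventions are warnings.

| rule | severity | meaning |
|------|----------|---------|
| E1 | error | subject of a vocabulary object property has no vocabulary type |
| E2 | error | object-property domain violation |
| E3 | error | range violation, checked only when the object is internal and typed |
| E4 | error | dangling internal `#fragment` reference (no statements about it) |
| E5 | error | node typed with an abstract class |
| W1 | warning | `owl:Class` used as a typing predicate (normalized to `rdf:type`); also multiple typing |
| W2 | warning | `location` not in letter+digits grid form (`"D4"`) |
| W3 | warning | `drill_site` not in `"integer,integer"` form (`"78,90"`) |
| W4 | warning | descriptor used with the unconventional value shape |
| W5 | warning | external reference (informational) |

Normalization decisions: typing statements written with `owl:Class` in
predicate position — a shorthand that appears in published triple listings —
are accepted on input and rewritten to `rdf:type` (`W1`); when a node
carries several vocabulary types, the first in canonical order wins for
domain/range checking and the rest raise `W1`. Range checks are skipped for
external or untyped objects because unresolved references are a feature of
the format, not a defect.

## RDF input/output and canonicalization

RDF/XML is the primary format (instance documents in the wild use it);
Turtle is offered for readability and N-Triples for diffing. Serialization
is deterministic: triples are emitted in canonical order — byte-wise
(radix) sort on subject, predicate, literal-flag, object, independent of
locale — and only the prefixes actually used are declared, sorted. Blank
nodes receive deterministic labels: each is keyed by the sorted set of its
incident triples with blank positions masked, ties broken by first
occurrence. This is not a full RDF canonicalization algorithm; it is
adequate because these documents carry at most a handful of blank nodes
(the `clinical_annotation` bundle pattern), and `graph_isomorphic()` falls
back to exhaustive bijection search over up to eight blank nodes.

Degenerate inputs are defined rather than accidental: an empty model
projects to an empty graph; an empty document parses to an empty graph;
duplicate statements collapse (set semantics); literals round-trip exactly,
including whitespace. Typed (`^^`) and language-tagged literals are read by
dropping the tag — the vocabulary never types its literals — and this is
the one deliberately lossy corner of the parser.

## The XML conversion dialect

The extract → structure → transform pipeline is implemented as a
programmatic transform of a pinned XML dialect (XSD in
`inst/extdata/tma-xml.xsd`): `tma > block > {slide, core}`, with cores under
a slide read as cores-on-slide and cores under a block as cores-in-block.
`donor_block` and `diagnosis_term` are attributes of block-level cores,
where the vocabulary's domains put those properties. A core-on-slide with
location `L` is linked `derived_from_core` to the core in the enclosing
block whose identifier ends with `core` + `L` — the `#coreD4` naming
convention — and no edge is emitted when there is no unique match.
TMA and block IRIs are minted absolute through the URI policy (they
simulate catalog documents); slides and cores become `#fragment` resources
of the output document's base. The `direction` setting chooses top-down
(default, whole-hierarchy), bottom-up, or both-direction hierarchy edges.
An XSLT stylesheet would be an equivalent engine; the programmatic transform
was chosen so the dialect checks (unique identifiers, nesting) and IRI
minting share code with the rest of the package.

## The synthetic-fixture generator

`generate_model()` is a pure function of a `synth_spec()`. Defaults model a
small production array: one block with a fully occupied 8 × 12 grid — 96
cores, the low end of the 100–1000 cores a working TMA carries — one slide
per block, drill sites uniform integer pairs in [0, 500], spreadsheet-style
grid addresses (`"D4"`), a three-term diagnosis pool attached to roughly
half the cores, and donor-block references minted under the example
institution's authority. Grid convention and coordinate range are declared
choices; the schema fixes no coordinate system.

What the generator emulates: multi-block arrays, grid-addressed cores,
per-slide core sections with `derived_from_core` provenance, external
donor-block and diagnosis references, and cross-document absolute IRIs whose
targets do not resolve. What it does not emulate: realistic staining or
scoring results (result values are opaque tokens), partially damaged or
missing cores, multi-sector grids, or clinical data models. Tests passing on
generated documents therefore demonstrate structural and serialization
correctness, not robustness to the full messiness of production exports.

`mutate_graph()` plants exactly one seeded corruption per call, one kind per
error rule (drop a typing, rewire a domain, retarget a range to a
wrong-class internal node, add a dangling fragment, retype abstract), which
gives the validator a detection suite with a known ground truth. A mutation
that a graph cannot host (e.g. a range retarget in a coreless document)
raises a mutation error rather than silently doing nothing.

Problem sizes used by the test suite and the acceptance script — twenty
arrays of one to five blocks on 8 × 12 grids with fill rates spanning 0 to
1, and fifty mutated documents (five rules × ten seeds) — keep every
property check exhaustive at the scale of a few thousand triples per
document.

## External links

`link_term()` adds the two-statement pattern `(subject, property, node)`,
`(node, rdf:type, term)` with auto-minted `#diagnosis1`-style fragment ids
(or blank nodes), and `link_experiment()` connects a `core_on_slide` to a
microarray-experiment IRI. The predicate for the experiment connection is
not fixed by the vocabulary's published description; we use `assay` — the
only assay-flavored property available — and expose it as an argument.

## Known limitations

* No OWL-DL reasoning: inverse materialization and domain/range checks are
  the only inference; no cardinality axioms, no imports closure.
* The RDF/XML parser covers the constructs the package emits plus typed
  nodes, `rdf:Description`, `rdf:ID`/`rdf:about`/`rdf:nodeID`,
  `rdf:resource` and one level of nested node elements — not the full
  RDF/XML grammar (no `rdf:parseType`, no property attributes).
* Turtle support is statement-oriented (`;`/`,` abbreviations are read,
  never written); no named graphs, no RDF-star.
* Resolvability of published URIs is the publisher's duty; the package
  neither hosts nor fetches.
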