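# Linking TMA resources to external-ontology terms. Term IRIs (NCI Thesaurus
# diagnoses, MGED experiment descriptions, ...) are opaque: they are never
# dereferenced, downloaded, or checked for resolvability.

TERM_LINK_PROPS <- c("diagnosis", "clinical_annotation", "result",
                     "assay", "protocol", "report_link")

#' Attach an external-ontology term to a resource
#'
#' Adds a typed intermediate node: `(subject, link_property, node)` and
#' `(node, rdf:type, term_iri)`. With `node_id = "auto"` the node is minted as
#' a `#<property><counter>` fragment of the document base (the `#diagnosis1`
#' pattern); a `_:` id yields the blank-node variant.
#'
#' @param graph A `tma_graph`.
#' @param subject IRI of a resource present in the graph (shorthand accepted).
#' @param link_property One of `diagnosis`, `clinical_annotation`, `result`,
#'   `assay`, `protocol`, `report_link`.
#' @param term_iri External class IRI (absolute or `prefix:local`).
#' @param node_id `"auto"`, a `#fragment`/absolute IRI, or a `_:` blank id.
#' @return The augmented graph (exactly two triples added).
#' @export
link_term <- function(graph, subject, link_property, term_iri,
                      node_id = "auto") {
  stopifnot(inherits(graph, "tma_graph"))
  if (!(link_property %in% TERM_LINK_PROPS)) {
    stop(sprintf("link error: unknown link property '%s'", link_property),
         call. = FALSE)
  }
  s <- expand_shorthand(subject, graph$nsmap)
  if (!(s %in% graph$triples$s)) {
    stop(sprintf("link error: subject '%s' not present in graph", s),
         call. = FALSE)
  }
  term <- expand_shorthand(term_iri, graph$nsmap)
  base <- graph$nsmap$base
  if (identical(node_id, "auto")) {
    if (is.na(base)) {
      stop("link error: auto node ids need a document base IRI", call. = FALSE)
    }
    pfx <- paste0(base, "#", link_property)
    existing <- unique(c(graph$triples$s, graph$triples$o[!graph$triples$o_lit]))
    cand <- existing[startsWith(existing, pfx)]
    used <- cand[grepl("^[0-9]+$", substring(cand, nchar(pfx) + 1L))]
    node <- paste0(base, "#", link_property, length(used) + 1L)
  } else if (is_blank(node_id)) {
    node <- node_id
  } else {
    node <- expand_shorthand(node_id, graph$nsmap)
  }
  graph <- add_triples(graph, s, paste0(NS_TMA, link_property), node)
  add_triples(graph, node, RDF_TYPE, term)
}

#' Link a core-on-slide to a microarray experiment
#'
#' Records that a core section was the sample of an externally described
#' experiment (e.g. an MGED-Ontology experiment instance): adds one triple
#' `(core_on_slide, assay, experiment_iri)`. The subject must be typed
#' `core_on_slide` in the graph. The predicate defaults to the vocabulary's
#' `assay` property and is configurable.
#'
#' @param graph A `tma_graph`.
#' @param core_on_slide IRI of a resource typed `tma:core_on_slide`.
#' @param experiment_iri Opaque external experiment IRI.
#' @param property Link predicate token; default `"assay"`.
#' @return The augmented graph.
#' @export
link_experiment <- function(graph, core_on_slide, experiment_iri,
                            property = "assay") {
  stopifnot(inherits(graph, "tma_graph"))
  s <- expand_shorthand(core_on_slide, graph$nsmap)
  df <- graph$triples
  typed <- df$s[df$p == RDF_TYPE & !df$o_lit &
                  df$o == paste0(NS_TMA, "core_on_slide")]
  if (!(s %in% typed)) {
    stop(sprintf("link error: '%s' is not typed core_on_slide", s),
         call. = FALSE)
  }
  if (!(property %in% TERM_LINK_PROPS)) {
    stop(sprintf("link error: unknown link property '%s'", property),
         call. = FALSE)
  }
  add_triples(graph, s, paste0(NS_TMA, property),
              expand_shorthand(experiment_iri, graph$nsmap))
}
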