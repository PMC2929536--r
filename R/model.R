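# Typed in-memory representation of a TMA hierarchy: nodes (array, blocks,
# slides, cores-in-block, cores-on-slide) with open annotation maps, plus
# object-property edges. External references (donor blocks, diagnosis terms,
# parent documents) are opaque IRIs and are never fetched.

#' Mark a value as a resource IRI
#'
#' Annotation values are plain strings (literals) by default; wrap a value
#' with `iri()` to store it as a resource reference instead. Datatype
#' properties accept either shape.
#'
#' @param x Absolute IRI or `#fragment`/`prefix:local` shorthand.
#' @return The string, classed `tma_iri`.
#' @export
iri <- function(x) structure(as.character(x), class = "tma_iri")

is_iri_value <- function(x) inherits(x, "tma_iri")

#' Create an empty TMA model
#'
#' @param vocab Vocabulary used for domain/range checking on insertion;
#'   defaults to [build_schema()].
#' @param nsmap Namespace map used to expand shorthand annotation property
#'   names and `iri()` values; defaults to [default_nsmap()].
#' @return An object of class `tma_model`.
#' @export
tma_model <- function(vocab = build_schema(), nsmap = default_nsmap()) {
  structure(list(nodes = list(), edges = empty_edges(), extra = empty_triples(),
                 vocab = vocab, nsmap = nsmap),
            class = "tma_model")
}

empty_edges <- function() {
  data.frame(s = character(), p = character(), o = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.tma_model <- function(x, ...) {
  cls <- vapply(x$nodes, `[[`, character(1), "schema_class")
  cat("<tma_model>\n")
  for (k in concrete_classes(x$vocab)) {
    cat(sprintf("  %s: %d\n", k, sum(cls == k)))
  }
  cat(sprintf("  edges: %d\n", nrow(x$edges)))
  invisible(x)
}

#' Count model nodes by class
#' @param model A `tma_model`.
#' @return Named integer vector over the concrete classes.
#' @export
node_counts <- function(model) {
  cls <- vapply(model$nodes, `[[`, character(1), "schema_class")
  out <- stats::setNames(integer(length(concrete_classes(model$vocab))),
                         concrete_classes(model$vocab))
  tab <- table(cls)
  out[names(tab)] <- as.integer(tab)
  out
}

normalize_ann_key <- function(key, vocab, nsmap) {
  if (key %in% annotation_properties(vocab)) return(key)
  expand_shorthand(key, nsmap)  # errors on bare unknown tokens
}

normalize_annotations <- function(annotations, vocab, nsmap) {
  if (!length(annotations)) return(list())
  if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
    stop("model error: annotations must be a named list", call. = FALSE)
  }
  out <- list()
  for (key in names(annotations)) {
    k <- normalize_ann_key(key, vocab, nsmap)
    vals <- annotations[[key]]
    if (!is.list(vals)) vals <- if (is_iri_value(vals)) list(vals) else as.list(vals)
    vals <- lapply(vals, function(v) {
      if (is_iri_value(v)) iri(expand_shorthand(unclass(v), nsmap))
      else as.character(v)
    })
    out[[k]] <- c(out[[k]], vals)
  }
  out
}

#' Add a node to a model
#'
#' @param model A `tma_model`.
#' @param schema_class Concrete class token (`tma`, `block`, `slide`,
#'   `core_in_block`, `core_on_slide`). Abstract classes are rejected.
#' @param iri Absolute IRI of the node (or `#fragment` shorthand, expanded
#'   against the model's namespace map). Must not already be present.
#' @param annotations Named list: datatype-property token (or external
#'   annotation shorthand such as `"dc:title"`) to value(s). Values are
#'   literals unless wrapped with [iri()].
#' @return The updated model.
#' @examples
#' m <- tma_model()
#' m <- add_node(m, "tma", "http://www.institutionXYZ.org/tma/000001",
#'               annotations = list("dc:title" = "All-Purpose Tissue Array"))
#' @export
add_node <- function(model, schema_class, iri, annotations = list()) {
  stopifnot(inherits(model, "tma_model"))
  if (schema_class %in% abstract_classes(model$vocab)) {
    stop(sprintf("model error: '%s' is an abstract class", schema_class),
         call. = FALSE)
  }
  if (!(schema_class %in% concrete_classes(model$vocab))) {
    stop(sprintf("model error: unknown class '%s'", schema_class), call. = FALSE)
  }
  node_iri <- expand_shorthand(iri, model$nsmap)
  if (node_iri %in% names(model$nodes)) {
    stop(sprintf("model error: duplicate iri '%s'", node_iri), call. = FALSE)
  }
  model$nodes[[node_iri]] <- list(
    iri = node_iri, schema_class = schema_class,
    annotations = normalize_annotations(annotations, model$vocab, model$nsmap))
  model
}

#' Annotate an existing node
#' @inheritParams add_node
#' @param iri IRI of a node already in the model.
#' @return The updated model.
#' @export
annotate_node <- function(model, iri, annotations) {
  node_iri <- expand_shorthand(iri, model$nsmap)
  if (!(node_iri %in% names(model$nodes))) {
    stop(sprintf("model error: unknown node '%s'", node_iri), call. = FALSE)
  }
  new <- normalize_annotations(annotations, model$vocab, model$nsmap)
  ann <- model$nodes[[node_iri]]$annotations
  for (k in names(new)) ann[[k]] <- c(ann[[k]], new[[k]])
  model$nodes[[node_iri]]$annotations <- ann
  model
}

#' Add an object-property edge
#'
#' The subject must be a model node and the property an object property.
#' Domain is always checked against the subject's class; range is checked only
#' when the object is also a model node — external targets (a donor block in
#' another repository's document, a parent TMA catalogued elsewhere) are
#' accepted as opaque IRIs.
#'
#' @param model A `tma_model`.
#' @param subject,object Node IRIs (shorthand accepted).
#' @param property Object-property token, e.g. `"includes_slide"`.
#' @return The updated model.
#' @export
add_edge <- function(model, subject, property, object) {
  stopifnot(inherits(model, "tma_model"))
  s <- expand_shorthand(subject, model$nsmap)
  o <- expand_shorthand(object, model$nsmap)
  prow <- vocab_property(model$vocab, property)
  if (prow$kind != "object") {
    stop(sprintf("edge error: '%s' is not an object property", property),
         call. = FALSE)
  }
  snode <- model$nodes[[s]]
  if (is.null(snode)) {
    stop(sprintf("edge error: subject '%s' not in model", s), call. = FALSE)
  }
  if (snode$schema_class != prow$domain) {
    stop(sprintf("edge error: domain violation: %s has domain %s, subject is a %s",
                 property, prow$domain, snode$schema_class), call. = FALSE)
  }
  onode <- model$nodes[[o]]
  if (!is.null(onode) && prow$range != "external" &&
      onode$schema_class != prow$range) {
    stop(sprintf("edge error: range violation: %s has range %s, object is a %s",
                 property, prow$range, onode$schema_class), call. = FALSE)
  }
  new <- data.frame(s = s, p = property, o = o, stringsAsFactors = FALSE)
  all <- rbind(model$edges, new)
  model$edges <- all[!duplicated(paste(all$s, all$p, all$o, sep = "\r")), ,
                     drop = FALSE]
  rownames(model$edges) <- NULL
  model
}

# vectorized edge insertion with the same checks as add_edge; used where many
# edges arrive at once (generator, from_graph)
add_edges_bulk <- function(model, s, p, o) {
  if (!length(s)) return(model)
  cls <- vapply(model$nodes, `[[`, character(1), "schema_class")
  pr <- model$vocab$properties
  prop_idx <- match(p, pr$local_name)
  if (anyNA(prop_idx) || any(pr$kind[prop_idx] != "object")) {
    stop("edge error: unknown or non-object property", call. = FALSE)
  }
  scls <- cls[s]
  if (anyNA(scls)) stop("edge error: subject not in model", call. = FALSE)
  bad <- scls != pr$domain[prop_idx]
  if (any(bad)) {
    stop(sprintf("edge error: domain violation for '%s'", p[which(bad)[1]]),
         call. = FALSE)
  }
  ocls <- cls[o]
  rng <- pr$range[prop_idx]
  bad <- !is.na(ocls) & rng != "external" & ocls != rng
  if (any(bad)) {
    stop(sprintf("edge error: range violation for '%s'", p[which(bad)[1]]),
         call. = FALSE)
  }
  all <- rbind(model$edges,
               data.frame(s = unname(s), p = unname(p), o = unname(o),
                          stringsAsFactors = FALSE))
  model$edges <- all[!duplicated(paste(all$s, all$p, all$o, sep = "\r")), ,
                     drop = FALSE]
  rownames(model$edges) <- NULL
  model
}

#' Project a model to a triple graph
#'
#' Emits one typing triple per node (`rdf:type`), one triple per annotation
#' value, one per edge, plus any verbatim extra triples the model carries
#' (e.g. term-node typings picked up by [from_graph()]). Inverse triples are
#' not added; see [materialize_inverses()].
#'
#' @param model A `tma_model`.
#' @param nsmap Namespace map for the resulting graph; defaults to the
#'   model's.
#' @return A `tma_graph`.
#' @export
to_graph <- function(model, nsmap = model$nsmap) {
  stopifnot(inherits(model, "tma_model"))
  ns <- model$vocab$namespace
  ann_props <- annotation_properties(model$vocab)
  ss <- character(); pp <- character(); oo <- character(); ll <- logical()
  push <- function(s, p, o, lit) {
    ss[[length(ss) + 1L]] <<- s; pp[[length(pp) + 1L]] <<- p
    oo[[length(oo) + 1L]] <<- o; ll[[length(ll) + 1L]] <<- lit
  }
  for (node in model$nodes) {
    push(node$iri, RDF_TYPE, paste0(ns, node$schema_class), FALSE)
    for (k in names(node$annotations)) {
      pred <- if (k %in% ann_props) paste0(ns, k) else k
      for (v in node$annotations[[k]]) {
        push(node$iri, pred, unclass(v), !is_iri_value(v))
      }
    }
  }
  g <- tma_graph(nsmap)
  if (length(ss)) g <- add_triples(g, ss, pp, oo, ll)
  if (nrow(model$edges)) {
    g <- add_triples(g, model$edges$s, paste0(ns, model$edges$p), model$edges$o)
  }
  if (nrow(model$extra)) {
    g <- add_triples(g, model$extra$s, model$extra$p, model$extra$o,
                     model$extra$o_lit)
  }
  g
}

#' Rebuild a model from an instance graph
#'
#' Nodes come from typing triples (the `owl:Class`-as-predicate shorthand is
#' normalized to `rdf:type` first), vocabulary object-property triples become
#' edges, annotation triples (vocabulary datatype properties or any foreign
#' predicate on a node) become annotations, and everything else is preserved
#' verbatim so that `to_graph(from_graph(g))` loses nothing.
#'
#' The graph must validate without errors against the vocabulary.
#'
#' @param graph A `tma_graph`.
#' @param vocab A `tma_vocabulary`.
#' @param base Document base IRI used for validation; defaults to the graph's.
#' @return A `tma_model`.
#' @export
from_graph <- function(graph, vocab = build_schema(), base = graph$nsmap$base) {
  graph <- normalize_typing(graph)
  report <- validate(graph, vocab, base)
  if (!report$valid) {
    stop(paste0("parse error: graph does not validate:\n",
                paste(format_findings(report$findings[
                  report$findings$severity == "error", , drop = FALSE]),
                  collapse = "\n")), call. = FALSE)
  }
  ns <- vocab$namespace
  df <- canonical_triples(graph)
  model <- tma_model(vocab = vocab, nsmap = graph$nsmap)
  typing <- df[df$p == RDF_TYPE & !df$o_lit & startsWith(df$o, ns), , drop = FALSE]
  typing <- typing[sub(ns, "", typing$o, fixed = TRUE) %in%
                     concrete_classes(vocab), , drop = FALSE]
  for (i in seq_len(nrow(typing))) {
    cls <- sub(ns, "", typing$o[i], fixed = TRUE)
    if (!(typing$s[i] %in% names(model$nodes))) {
      model <- add_node(model, cls, typing$s[i])
    }
  }
  node_iris <- names(model$nodes)
  typing_rows <- paste(typing$s, typing$p, typing$o, sep = "\r")
  obj_props <- object_properties(vocab)
  ann_props <- annotation_properties(vocab)
  keys <- triple_key(model$extra)  # empty
  row_key <- paste(df$s, df$p, df$o, sep = "\r")
  tok <- ifelse(startsWith(df$p, ns),
                substr(df$p, nchar(ns) + 1L, nchar(df$p)), NA_character_)
  is_typing <- df$p == RDF_TYPE & row_key %in% typing_rows
  is_edge <- !is_typing & !is.na(tok) & tok %in% obj_props & !df$o_lit
  is_ann <- !is_typing & !is_edge & df$s %in% node_iris & df$p != RDF_TYPE
  is_extra <- !is_typing & !is_edge & !is_ann
  model <- add_edges_bulk(model, df$s[is_edge], tok[is_edge], df$o[is_edge])
  for (i in which(is_ann)) {
    key <- if (!is.na(tok[i]) && tok[i] %in% ann_props) tok[i] else df$p[i]
    val <- if (df$o_lit[i]) df$o[i] else iri(df$o[i])
    ann <- model$nodes[[df$s[i]]]$annotations
    ann[[key]] <- c(ann[[key]], list(val))
    model$nodes[[df$s[i]]]$annotations <- ann
  }
  model$extra <- df[is_extra, , drop = FALSE]
  rownames(model$extra) <- NULL
  model
}

#' Test two models for equality
#'
#' Compares node sets (IRIs and classes), per-node annotation multisets, edge
#' sets and extra triples, all order-insensitively.
#'
#' @param m1,m2 `tma_model` objects.
#' @return Logical scalar.
#' @export
model_equal <- function(m1, m2) {
  norm_node <- function(node) {
    ann <- node$annotations
    if (length(ann)) ann <- ann[order(names(ann))]
    ann <- lapply(ann, function(vals) {
      sort(vapply(vals, function(v)
        paste0(if (is_iri_value(v)) "I" else "L", unclass(v)), character(1)),
        method = "radix")
    })
    list(iri = node$iri, schema_class = node$schema_class, annotations = ann)
  }
  norm <- function(m) {
    nodes <- lapply(m$nodes, norm_node)
    if (length(nodes)) nodes <- nodes[order(names(nodes), method = "radix")]
    edges <- sort(paste(m$edges$s, m$edges$p, m$edges$o, sep = "\r"),
                  method = "radix")
    extra <- sort(triple_key(m$extra), method = "radix")
    list(nodes = nodes, edges = edges, extra = extra)
  }
  isTRUE(all.equal(norm(m1), norm(m2), check.attributes = FALSE))
}
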