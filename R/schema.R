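# The minimal TMA vocabulary: 7 classes (two abstract parents), 10 object
# properties (four inverse pairs along the tma > block > slide > core
# hierarchy), and 15 annotation-style datatype properties. The datatype
# properties carry "literal-or-resource" ranges: instance data legitimately
# uses either value shape (a diagnosis points at a term node, a repository is
# a plain string), so neither is rejected.

TMA_CLASS_RANK <- c(tma = 0L, block = 1L, slide = 2L,
                    core_in_block = 3L, core_on_slide = 3L)

TMA_ANNOTATION_PROPS <- c("status", "level", "size", "thickness",
                          "core_spacing", "location", "diagnosis",
                          "clinical_annotation", "drill_site", "protocol",
                          "report_link", "control", "result", "repository",
                          "assay")

#' Build the minimal TMA vocabulary
#'
#' Constructs the complete schema: the abstract parents `repository_product`
#' and `experimental_component`; the concrete classes `tma`, `block`, `slide`,
#' `core_in_block`, `core_on_slide`; the ten hierarchy object properties with
#' their domains, ranges and inverse pairings; and the fifteen annotation
#' properties.
#'
#' The assignment of concrete classes to abstract parents can be overridden:
#' by default `tma`, `block` and `slide` (dispensable physical artifacts) sit
#' under `repository_product`, while the two core classes (the experimental
#' units) sit under `experimental_component`.
#'
#' @param parent_map Named character vector mapping each concrete class to its
#'   abstract parent.
#' @param namespace Vocabulary namespace IRI.
#' @return An object of class `tma_vocabulary` with elements `classes`
#'   (data.frame: `local_name`, `parent`, `abstract`), `properties`
#'   (data.frame: `local_name`, `kind`, `domain`, `range`, `inverse`,
#'   `direction`) and `namespace`.
#' @examples
#' v <- build_schema()
#' inverse_of(v, "includes_slide")
#' @export
build_schema <- function(parent_map = c(tma = "repository_product",
                                        block = "repository_product",
                                        slide = "repository_product",
                                        core_in_block = "experimental_component",
                                        core_on_slide = "experimental_component"),
                         namespace = NS_TMA) {
  concrete <- names(TMA_CLASS_RANK)
  abstracts <- c("repository_product", "experimental_component")
  if (!setequal(names(parent_map), concrete) ||
      !all(parent_map %in% abstracts)) {
    stop("parent_map must assign every concrete class to an abstract parent",
         call. = FALSE)
  }
  classes <- data.frame(
    local_name = c(abstracts, concrete),
    parent = c(NA_character_, NA_character_, unname(parent_map[concrete])),
    abstract = c(TRUE, TRUE, rep(FALSE, length(concrete))),
    stringsAsFactors = FALSE)

  op <- function(name, domain, range, inverse = NA_character_) {
    data.frame(local_name = name, kind = "object", domain = domain,
               range = range, inverse = inverse, stringsAsFactors = FALSE)
  }
  obj <- rbind(
    op("includes_block",     "tma",           "block",         "included_in_tma"),
    op("included_in_tma",    "block",         "tma",           "includes_block"),
    op("includes_slide",     "block",         "slide",         "cut_from_block"),
    op("cut_from_block",     "slide",         "block",         "includes_slide"),
    op("block_includes_core","block",         "core_in_block", "included_in_block"),
    op("included_in_block",  "core_in_block", "block",         "block_includes_core"),
    op("slide_includes_core","slide",         "core_on_slide", "affixed_to_slide"),
    op("affixed_to_slide",   "core_on_slide", "slide",         "slide_includes_core"),
    op("derived_from_core",  "core_on_slide", "core_in_block", NA_character_),
    op("donor_block",        "core_in_block", "external",      NA_character_))
  # paired properties run either down the hierarchy (container -> part) or up
  rank_of <- function(cls) TMA_CLASS_RANK[cls]
  obj$direction <- ifelse(is.na(obj$inverse), "none",
                          ifelse(rank_of(obj$domain) < rank_of(obj$range),
                                 "top_down", "bottom_up"))
  ann <- data.frame(local_name = TMA_ANNOTATION_PROPS, kind = "annotation",
                    domain = "any", range = "literal-or-resource",
                    inverse = NA_character_, direction = "none",
                    stringsAsFactors = FALSE)
  properties <- rbind(obj, ann)
  rownames(classes) <- rownames(properties) <- NULL
  structure(list(classes = classes, properties = properties,
                 namespace = namespace),
            class = "tma_vocabulary")
}

#' @export
print.tma_vocabulary <- function(x, ...) {
  cat(sprintf("<tma_vocabulary> %d classes, %d object properties, %d annotation properties\n",
              nrow(x$classes),
              sum(x$properties$kind == "object"),
              sum(x$properties$kind == "annotation")))
  cat("namespace:", x$namespace, "\n")
  invisible(x)
}

vocab_property <- function(vocab, property) {
  row <- vocab$properties[vocab$properties$local_name == property, , drop = FALSE]
  if (!nrow(row)) {
    stop(sprintf("lookup error: unknown property '%s'", property), call. = FALSE)
  }
  row
}

#' Look up the inverse of a paired object property
#'
#' @param vocab A [build_schema()] vocabulary.
#' @param property Property local name; must exist in the vocabulary.
#' @return The paired property's local name, or `NA` for unpaired properties.
#' @export
inverse_of <- function(vocab, property) {
  vocab_property(vocab, property)$inverse
}

concrete_classes <- function(vocab) {
  vocab$classes$local_name[!vocab$classes$abstract]
}

abstract_classes <- function(vocab) {
  vocab$classes$local_name[vocab$classes$abstract]
}

object_properties <- function(vocab) {
  vocab$properties$local_name[vocab$properties$kind == "object"]
}

annotation_properties <- function(vocab) {
  vocab$properties$local_name[vocab$properties$kind == "annotation"]
}

#' Emit the vocabulary as an OWL schema document
#'
#' Declares each class (with a subclass axiom to its abstract parent), each
#' object property with domain, range and inverse axioms, and each annotation
#' property. Re-parsing the document with [parse_schema_document()] rebuilds a
#' vocabulary equal to the input.
#'
#' @param vocab A `tma_vocabulary`.
#' @param format `"rdf-xml"` (default) or `"turtle"`.
#' @return A character string: the schema document.
#' @export
emit_schema_document <- function(vocab, format = "rdf-xml") {
  check_format(format)
  if (format == "ntriples") stop("format error: unsupported format", call. = FALSE)
  ns <- vocab$namespace
  nsmap <- tma_nsmap(c(tma = ns, rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL))
  g <- tma_graph(nsmap)
  cls <- vocab$classes
  g <- add_triples(g, paste0(ns, cls$local_name), RDF_TYPE, OWL_CLASS)
  sub <- cls[!is.na(cls$parent), , drop = FALSE]
  g <- add_triples(g, paste0(ns, sub$local_name),
                   paste0(NS_RDFS, "subClassOf"), paste0(ns, sub$parent))
  pr <- vocab$properties
  obj <- pr[pr$kind == "object", , drop = FALSE]
  g <- add_triples(g, paste0(ns, obj$local_name), RDF_TYPE,
                   paste0(NS_OWL, "ObjectProperty"))
  g <- add_triples(g, paste0(ns, obj$local_name),
                   paste0(NS_RDFS, "domain"), paste0(ns, obj$domain))
  ranged <- obj[obj$range != "external", , drop = FALSE]
  g <- add_triples(g, paste0(ns, ranged$local_name),
                   paste0(NS_RDFS, "range"), paste0(ns, ranged$range))
  ext <- obj[obj$range == "external", , drop = FALSE]
  if (nrow(ext)) {
    g <- add_triples(g, paste0(ns, ext$local_name),
                     paste0(NS_RDFS, "range"), paste0(NS_RDFS, "Resource"))
  }
  paired <- obj[!is.na(obj$inverse), , drop = FALSE]
  g <- add_triples(g, paste0(ns, paired$local_name),
                   paste0(NS_OWL, "inverseOf"), paste0(ns, paired$inverse))
  ann <- pr[pr$kind == "annotation", , drop = FALSE]
  g <- add_triples(g, paste0(ns, ann$local_name), RDF_TYPE,
                   paste0(NS_OWL, "AnnotationProperty"))
  serialize_rdf(g, format)
}

#' Rebuild a vocabulary from an emitted schema document
#'
#' Inverse of [emit_schema_document()]: abstract classes are the subclass
#' roots, inverse pairings come from `owl:inverseOf`, an `rdfs:Resource` range
#' reads back as "external", and paired-property directions are recovered from
#' the hierarchy ranks of domain and range.
#'
#' @param text Schema document content.
#' @param format `"rdf-xml"` or `"turtle"`.
#' @return A `tma_vocabulary`.
#' @export
parse_schema_document <- function(text, format = "rdf-xml") {
  g <- parse_rdf(text, format)
  df <- g$triples
  local <- function(iri) sub("^.*[#/]", "", iri)
  ns_of <- function(iri) sub("[^#/]*$", "", iri)
  cls_iris <- df$s[df$p == RDF_TYPE & df$o == OWL_CLASS]
  if (!length(cls_iris)) stop("parse error: no owl:Class declarations",
                              call. = FALSE)
  namespace <- ns_of(cls_iris[1])
  parents <- stats::setNames(
    local(df$o[df$p == paste0(NS_RDFS, "subClassOf")]),
    local(df$s[df$p == paste0(NS_RDFS, "subClassOf")]))
  cls_names <- local(cls_iris)
  classes <- data.frame(
    local_name = cls_names,
    parent = ifelse(cls_names %in% names(parents),
                    unname(parents[cls_names]), NA_character_),
    abstract = !(cls_names %in% names(parents)),
    stringsAsFactors = FALSE)
  obj_iris <- df$s[df$p == RDF_TYPE & df$o == paste0(NS_OWL, "ObjectProperty")]
  domains <- stats::setNames(local(df$o[df$p == paste0(NS_RDFS, "domain")]),
                             local(df$s[df$p == paste0(NS_RDFS, "domain")]))
  rng_s <- local(df$s[df$p == paste0(NS_RDFS, "range")])
  rng_o <- df$o[df$p == paste0(NS_RDFS, "range")]
  ranges <- stats::setNames(
    ifelse(rng_o == paste0(NS_RDFS, "Resource"), "external", local(rng_o)),
    rng_s)
  invs <- stats::setNames(local(df$o[df$p == paste0(NS_OWL, "inverseOf")]),
                          local(df$s[df$p == paste0(NS_OWL, "inverseOf")]))
  obj_names <- local(obj_iris)
  obj <- data.frame(local_name = obj_names, kind = "object",
                    domain = unname(domains[obj_names]),
                    range = unname(ranges[obj_names]),
                    inverse = ifelse(obj_names %in% names(invs),
                                     unname(invs[obj_names]), NA_character_),
                    stringsAsFactors = FALSE)
  rank_of <- function(cls) {
    r <- TMA_CLASS_RANK[cls]
    ifelse(is.na(r), NA_integer_, r)
  }
  obj$direction <- ifelse(is.na(obj$inverse), "none",
                          ifelse(rank_of(obj$domain) < rank_of(obj$range),
                                 "top_down", "bottom_up"))
  ann_iris <- df$s[df$p == RDF_TYPE & df$o == paste0(NS_OWL, "AnnotationProperty")]
  ann <- data.frame(local_name = local(ann_iris), kind = "annotation",
                    domain = "any", range = "literal-or-resource",
                    inverse = NA_character_, direction = "none",
                    stringsAsFactors = FALSE)
  canon <- build_schema()
  reorder <- function(df, ref) {
    df[order(match(df$local_name, ref, nomatch = length(ref) + 1L),
             df$local_name), , drop = FALSE]
  }
  classes <- reorder(classes, canon$classes$local_name)
  props <- reorder(rbind(obj, ann), canon$properties$local_name)
  rownames(classes) <- rownames(props) <- NULL
  structure(list(classes = classes, properties = props, namespace = namespace),
            class = "tma_vocabulary")
}

#' Test two vocabularies for equality
#' @param v1,v2 `tma_vocabulary` objects.
#' @return Logical scalar.
#' @export
vocab_equal <- function(v1, v2) {
  norm <- function(v) {
    list(classes = v$classes[order(v$classes$local_name), , drop = FALSE],
         properties = v$properties[order(v$properties$local_name), , drop = FALSE],
         namespace = v$namespace)
  }
  a <- norm(v1); b <- norm(v2)
  rownames(a$classes) <- rownames(b$classes) <- NULL
  rownames(a$properties) <- rownames(b$properties) <- NULL
  isTRUE(all.equal(a, b, check.attributes = TRUE))
}
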