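# The three-step extraction pipeline, step 2 -> step 3: a well-defined TMA XML
# document in, an OWL instance graph out. The XML dialect (shipped as an XSD in
# inst/extdata/tma-xml.xsd) is:
#
#   <tma identifier="000001" title="..." creator="..." repository="...">
#     <block identifier="RP2008-325">
#       <slide identifier="slide058">
#         <core identifier="slide058-D4" location="D4"/>   <!-- core on slide -->
#       </slide>
#       <core identifier="coreD4" location="D4" drill_site="78,90"
#             donor_block="RP2007-228" diagnosis_term="http://..."/>
#     </block>                                             <!-- core in block -->
#   </tma>
#
# Cores nested under a slide are cores-on-slide; cores directly under a block
# are cores-in-block. A core-on-slide with location L is linked
# derived_from_core to the core in the enclosing block whose identifier ends
# with "core" + L (the "#coreD4" naming convention). Unknown child elements of
# tma/block/core are carried along as datatype-property candidates.

TMA_XML_STRUCTURAL <- c("tma", "block", "slide", "core")

#' Parse a TMA XML document
#'
#' Validates structure against the dialect: `tma > block > {slide, core}`,
#' `slide > core`, identifiers unique per element kind. Unknown simple child
#' elements are preserved as annotation candidates.
#'
#' @param x Document content (character or raw) or an `xml2` document.
#' @return An object of class `tma_xml_document`: nested lists mirroring the
#'   dialect.
#' @export
parse_tma_xml <- function(x) {
  if (is.raw(x)) x <- rawToChar(x)
  doc <- if (inherits(x, "xml_document")) x else
    tryCatch(xml2::read_xml(x),
             error = function(e) stop(sprintf("parse error: %s",
                                              conditionMessage(e)),
                                      call. = FALSE))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "tma") {
    stop("dialect error: root element must be <tma>", call. = FALSE)
  }
  seen <- new.env(parent = emptyenv())
  attr_of <- function(at, key) if (key %in% names(at)) at[[key]] else NA
  note_id <- function(kind, id) {
    if (length(id) != 1L || is.na(id) || !nzchar(id)) {
      stop(sprintf("dialect error: <%s> element without identifier", kind),
           call. = FALSE)
    }
    key <- paste0(kind, "\r", id)
    if (!is.null(seen[[key]])) {
      stop(sprintf("dialect error: duplicate %s identifier '%s'", kind, id),
           call. = FALSE)
    }
    assign(key, TRUE, envir = seen)
    id
  }
  annotations_of <- function(node, skip = TMA_XML_STRUCTURAL) {
    out <- list()
    for (ch in xml2::xml_children(node)) {
      nm <- xml2::xml_name(ch)
      if (nm %in% skip) next
      if (length(xml2::xml_children(ch))) {
        stop(sprintf("dialect error: unexpected nested element <%s>", nm),
             call. = FALSE)
      }
      out[[nm]] <- c(out[[nm]], xml2::xml_text(ch))
    }
    out
  }
  parse_core <- function(node, kind) {
    at <- xml2::xml_attrs(node)
    for (ch in xml2::xml_children(node)) {
      if (xml2::xml_name(ch) %in% TMA_XML_STRUCTURAL) {
        stop(sprintf("dialect error: <%s> nested under <core>",
                     xml2::xml_name(ch)), call. = FALSE)
      }
    }
    list(identifier = note_id(paste0("core_", kind), attr_of(at, "identifier")),
         location = attr_of(at, "location"),
         drill_site = attr_of(at, "drill_site"),
         donor_block = attr_of(at, "donor_block"),
         diagnosis_term = attr_of(at, "diagnosis_term"),
         annotations = annotations_of(node))
  }
  parse_slide <- function(node) {
    at <- xml2::xml_attrs(node)
    cores <- list()
    for (ch in xml2::xml_children(node)) {
      nm <- xml2::xml_name(ch)
      if (nm == "core") {
        cores[[length(cores) + 1L]] <- parse_core(ch, "on_slide")
      } else if (nm %in% TMA_XML_STRUCTURAL) {
        stop(sprintf("dialect error: <%s> nested under <slide>", nm),
             call. = FALSE)
      }
    }
    list(identifier = note_id("slide", attr_of(at, "identifier")),
         cores = cores, annotations = annotations_of(node))
  }
  parse_block <- function(node) {
    at <- xml2::xml_attrs(node)
    slides <- list(); cores <- list()
    for (ch in xml2::xml_children(node)) {
      nm <- xml2::xml_name(ch)
      if (nm == "slide") {
        slides[[length(slides) + 1L]] <- parse_slide(ch)
      } else if (nm == "core") {
        cores[[length(cores) + 1L]] <- parse_core(ch, "in_block")
      } else if (nm == "tma" || nm == "block") {
        stop(sprintf("dialect error: <%s> nested under <block>", nm),
             call. = FALSE)
      }
    }
    list(identifier = note_id("block", attr_of(at, "identifier")),
         slides = slides, cores = cores, annotations = annotations_of(node))
  }
  at <- xml2::xml_attrs(root)
  blocks <- list()
  for (ch in xml2::xml_children(root)) {
    nm <- xml2::xml_name(ch)
    if (nm == "block") {
      blocks[[length(blocks) + 1L]] <- parse_block(ch)
    } else if (nm %in% c("slide", "core")) {
      stop(sprintf("dialect error: <%s> nested directly under <tma>", nm),
           call. = FALSE)
    }
  }
  getat <- function(k) attr_of(at, k)
  structure(list(identifier = note_id("tma", attr_of(at, "identifier")),
                 title = getat("title"), creator = getat("creator"),
                 repository = getat("repository"),
                 blocks = blocks, annotations = annotations_of(root)),
            class = "tma_xml_document")
}

#' @export
print.tma_xml_document <- function(x, ...) {
  n_slides <- sum(vapply(x$blocks, function(b) length(b$slides), integer(1)))
  n_bc <- sum(vapply(x$blocks, function(b) length(b$cores), integer(1)))
  n_sc <- sum(vapply(x$blocks, function(b)
    sum(vapply(b$slides, function(s) length(s$cores), integer(1))), integer(1)))
  cat(sprintf("<tma_xml_document> tma %s: %d block(s), %d slide(s), %d block core(s), %d slide core(s)\n",
              x$identifier, length(x$blocks), n_slides, n_bc, n_sc))
  invisible(x)
}

#' Count the entities of a parsed TMA XML document
#' @param xml A `tma_xml_document`.
#' @return Integer: tma + blocks + slides + cores (both kinds).
#' @export
xml_entity_count <- function(xml) {
  1L + length(xml$blocks) +
    sum(vapply(xml$blocks, function(b)
      length(b$slides) + length(b$cores) +
        sum(vapply(b$slides, function(s) length(s$cores), integer(1))),
      integer(1)))
}

#' Conversion configuration
#'
#' @param policy A [uri_policy()] used to mint TMA and block URIs (absolute,
#'   simulating catalog documents at those addresses).
#' @param nsmap A [tma_nsmap()] with a base IRI; slides and cores are minted
#'   as `#fragment` resources of the base document.
#' @param direction Which hierarchy edges to emit: `"top_down"` (default, for
#'   whole-hierarchy documents), `"bottom_up"`, or `"both"`.
#' @return An object of class `tma_conversion_config`.
#' @export
conversion_config <- function(policy, nsmap, direction = "top_down") {
  if (!direction %in% c("top_down", "bottom_up", "both")) {
    stop("direction must be top_down, bottom_up, or both", call. = FALSE)
  }
  if (is.na(nsmap$base)) {
    stop("conversion requires a document base IRI in the namespace map",
         call. = FALSE)
  }
  structure(list(policy = policy, nsmap = nsmap, direction = direction),
            class = "tma_conversion_config")
}

edge_for_direction <- function(p, direction, vocab) {
  prow <- vocab_property(vocab, p)
  if (is.na(prow$inverse)) return(p)
  switch(direction,
         both = c(p, NA),  # caller adds both directions itself
         top_down = if (prow$direction == "top_down") p else prow$inverse,
         bottom_up = if (prow$direction == "bottom_up") p else prow$inverse)
}

#' Convert a TMA XML document to an OWL instance graph
#'
#' Step 3 of the extraction pipeline, as a programmatic transform. Every
#' entity is minted an IRI (domain-meaningful identifier as key): TMA and
#' block URIs via the policy's path templates, slides and cores as fragments
#' of the document base. Typing, annotation and hierarchy triples are emitted
#' in the configured direction; a core-on-slide is linked `derived_from_core`
#' to the corresponding core in the enclosing block when their identifiers
#' correspond.
#'
#' @param xml A `tma_xml_document` (or raw/character XML, parsed first).
#' @param config A [conversion_config()].
#' @param vocab A `tma_vocabulary`.
#' @return A `tma_graph`.
#' @export
convert_tma_xml <- function(xml, config, vocab = build_schema()) {
  if (!inherits(xml, "tma_xml_document")) xml <- parse_tma_xml(xml)
  stopifnot(inherits(config, "tma_conversion_config"))
  ns <- vocab$namespace
  base <- config$nsmap$base
  frag <- function(id) paste0(base, "#", id)
  minted <- character()
  mint1 <- function(cls, key, fragment = FALSE) {
    u <- if (fragment) frag(key) else mint_class_uri(config$policy, cls, key)
    if (u %in% minted) {
      stop(sprintf("conversion error: identifier collision at '%s'", u),
           call. = FALSE)
    }
    minted <<- c(minted, u)
    u
  }
  g <- tma_graph(config$nsmap)
  typ <- function(u, cls) add_triples(g, u, RDF_TYPE, paste0(ns, cls))
  ann <- function(u, prop, val) {
    pred <- if (prop %in% annotation_properties(vocab)) paste0(ns, prop)
            else expand_shorthand(prop, config$nsmap)
    add_triples(g, u, pred, val, TRUE)
  }
  edge <- function(su, p, ou) {
    prow <- vocab_property(vocab, p)
    dirs <- if (is.na(prow$inverse)) p
            else if (config$direction == "both") c(p, prow$inverse)
            else if (prow$direction == config$direction) p
            else prow$inverse
    for (d in dirs) {
      if (d == p) g <<- add_triples(g, su, paste0(ns, d), ou)
      else g <<- add_triples(g, ou, paste0(ns, d), su)
    }
    g
  }
  tma_uri <- mint1("tma", xml$identifier)
  g <- typ(tma_uri, "tma")
  if (!is.na(xml$title)) g <- ann(tma_uri, "dc:title", xml$title)
  if (!is.na(xml$creator)) g <- ann(tma_uri, "dc:creator", xml$creator)
  if (!is.na(xml$repository)) g <- ann(tma_uri, "repository", xml$repository)
  for (k in names(xml$annotations)) {
    for (v in xml$annotations[[k]]) g <- ann(tma_uri, k, v)
  }
  ext_iri <- function(x, cls) {
    if (is_absolute_iri(x)) x else mint_class_uri(config$policy, cls, x)
  }
  for (blk in xml$blocks) {
    block_uri <- mint1("block", blk$identifier)
    g <- typ(block_uri, "block")
    for (k in names(blk$annotations)) {
      for (v in blk$annotations[[k]]) g <- ann(block_uri, k, v)
    }
    g <- edge(tma_uri, "includes_block", block_uri)
    core_uri_by_id <- character()
    for (core in blk$cores) {
      core_uri <- mint1("core_in_block", core$identifier, fragment = TRUE)
      core_uri_by_id[[core$identifier]] <- core_uri
      g <- typ(core_uri, "core_in_block")
      if (!is.na(core$location)) g <- ann(core_uri, "location", core$location)
      if (!is.na(core$drill_site)) g <- ann(core_uri, "drill_site", core$drill_site)
      if (!is.na(core$donor_block)) {
        g <- add_triples(g, core_uri, paste0(ns, "donor_block"),
                         ext_iri(core$donor_block, "block"))
      }
      if (!is.na(core$diagnosis_term)) {
        g <- add_triples(g, core_uri, paste0(ns, "diagnosis"),
                         expand_shorthand(core$diagnosis_term, config$nsmap))
      }
      for (k in names(core$annotations)) {
        for (v in core$annotations[[k]]) g <- ann(core_uri, k, v)
      }
      g <- edge(block_uri, "block_includes_core", core_uri)
    }
    for (sl in blk$slides) {
      slide_uri <- mint1("slide", sl$identifier, fragment = TRUE)
      g <- typ(slide_uri, "slide")
      for (k in names(sl$annotations)) {
        for (v in sl$annotations[[k]]) g <- ann(slide_uri, k, v)
      }
      g <- edge(block_uri, "includes_slide", slide_uri)
      for (core in sl$cores) {
        core_uri <- mint1("core_on_slide", core$identifier, fragment = TRUE)
        g <- typ(core_uri, "core_on_slide")
        if (!is.na(core$location)) g <- ann(core_uri, "location", core$location)
        for (k in names(core$annotations)) {
          for (v in core$annotations[[k]]) g <- ann(core_uri, k, v)
        }
        g <- edge(slide_uri, "slide_includes_core", core_uri)
        if (!is.na(core$location)) {
          hit <- names(core_uri_by_id)[endsWith(names(core_uri_by_id),
                                                paste0("core", core$location))]
          if (length(hit) == 1L) {
            g <- add_triples(g, core_uri, paste0(ns, "derived_from_core"),
                             core_uri_by_id[[hit]])
          }
        }
      }
    }
  }
  g
}
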