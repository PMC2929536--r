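# Deterministic synthetic TMA fixtures: typed models, their XML renderings,
# and rule-targeted graph corruptions for exercising the validator. Everything
# is a pure function of the spec (seed included); no external data.
#
# Conventions (the schema fixes no coordinate system): grid locations use the
# spreadsheet form row-letter + column-number ("D4"); drill sites are uniform
# integer pairs in [0, 500] ("78,90").

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic TMA specification
#'
#' Defaults describe a small single-block array with a fully occupied 8 x 12
#' grid (96 cores, the low end of the 100-1000 cores a production TMA
#' carries), one slide cut from the block, and a three-term diagnosis pool.
#'
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @param n_blocks Number of blocks in the array.
#' @param grid_rows,grid_cols Core grid dimensions (rows are letters, max 26).
#' @param slides_per_block Slides sectioned from each block.
#' @param fill_rate Fraction of grid cells occupied, in `[0, 1]`.
#' @param diagnosis_pool Character vector of external diagnosis term IRIs.
#' @param annotation_noise Add random opaque `status`/`result` annotations.
#' @return An object of class `tma_synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_blocks = 1L, grid_rows = 8L,
                       grid_cols = 12L, slides_per_block = 1L,
                       fill_rate = 1.0,
                       diagnosis_pool = c(
                         "http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#Prostate_Carcinoma",
                         "http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#Breast_Carcinoma",
                         "http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#Colon_Carcinoma"),
                       annotation_noise = FALSE) {
  stopifnot(grid_rows >= 0, grid_rows <= 26, grid_cols >= 0,
            n_blocks >= 0, slides_per_block >= 0,
            fill_rate >= 0, fill_rate <= 1)
  structure(list(seed = as.integer(seed), n_blocks = as.integer(n_blocks),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 slides_per_block = as.integer(slides_per_block),
                 fill_rate = fill_rate, diagnosis_pool = diagnosis_pool,
                 annotation_noise = isTRUE(annotation_noise)),
            class = "tma_synth_spec")
}

#' Default URI policy for synthetic documents
#' @return A [uri_policy()] under the example institution's authority.
#' @export
synth_policy <- function() {
  uri_policy("www.institutionXYZ.org",
             path_templates = list(tma = "tma", block = "block"))
}

#' Default namespace map for a synthetic document
#' @param seed Seed identifying the simulated document.
#' @return A [default_nsmap()] with a seed-specific base IRI.
#' @export
synth_nsmap <- function(seed = 1L) {
  default_nsmap(base = sprintf("http://www.the_url_here.org/tma_synth%04d.rdf",
                               as.integer(seed) %% 10000L))
}

#' Generate a synthetic TMA model
#'
#' One array node; `n_blocks` blocks, each with `slides_per_block` slides and
#' `round(fill_rate * grid_rows * grid_cols)` cores at distinct grid
#' locations. Each slide carries one core-on-slide per occupied cell, linked
#' `derived_from_core` to the block core. Identical spec yields an identical
#' model.
#'
#' @param spec A [synth_spec()].
#' @param policy A [uri_policy()]; TMA and block URIs are absolute.
#' @param nsmap Namespace map with base IRI; slides and cores are fragments.
#' @return A `tma_model`.
#' @export
generate_model <- function(spec, policy = synth_policy(),
                           nsmap = synth_nsmap(spec$seed)) {
  stopifnot(inherits(spec, "tma_synth_spec"))
  if (is.na(nsmap$base)) stop("generation error: nsmap needs a base IRI",
                              call. = FALSE)
  n_cells <- spec$grid_rows * spec$grid_cols
  k <- round(spec$fill_rate * n_cells)
  if (k > n_cells) stop("generation error: more cores than grid cells",
                        call. = FALSE)
  with_seed(spec$seed, {
    m <- tma_model(nsmap = nsmap)
    es <- character(); ep <- character(); eo <- character()
    edge <- function(s, p, o) {
      es[[length(es) + 1L]] <<- s; ep[[length(ep) + 1L]] <<- p
      eo[[length(eo) + 1L]] <<- o
    }
    tma_id <- sprintf("%06d", spec$seed %% 1000000L)
    tma_uri <- mint_class_uri(policy, "tma", tma_id)
    m <- add_node(m, "tma", tma_uri, annotations = list(
      "dc:title" = sprintf("Synthetic Tissue Array %s", tma_id),
      repository = "Generic Tissue Bank"))
    slide_no <- 0L
    for (b in seq_len(spec$n_blocks)) {
      blk_id <- sprintf("RP%04d-%03d", 2000L + sample(26L, 1L),
                        sample(999L, 1L) + b)
      blk_uri <- mint_class_uri(policy, "block", blk_id)
      m <- add_node(m, "block", blk_uri)
      edge(tma_uri, "includes_block", blk_uri)
      cells <- sort(sample(n_cells, k))
      locs <- paste0(LETTERS[(cells - 1L) %/% spec$grid_cols + 1L],
                     (cells - 1L) %% spec$grid_cols + 1L)
      core_uris <- character(length(locs))
      for (j in seq_along(locs)) {
        core_id <- paste0(blk_id, "-core", locs[j])
        core_uri <- paste0(nsmap$base, "#", core_id)
        ann <- list(drill_site = paste0(sample(0:500, 1L), ",",
                                        sample(0:500, 1L)),
                    repository = "Generic Tissue Bank")
        if (length(spec$diagnosis_pool) && stats::runif(1) < 0.5) {
          ann$diagnosis <- iri(sample(spec$diagnosis_pool, 1L))
        }
        if (spec$annotation_noise) {
          ann$status <- sample(c("ok", "depleted", "damaged"), 1L)
          ann$result <- sprintf("score_%d", sample(0:3, 1L))
        }
        m <- add_node(m, "core_in_block", core_uri, annotations = ann)
        edge(blk_uri, "block_includes_core", core_uri)
        edge(core_uri, "donor_block",
             mint_uri(policy, "block",
                      sprintf("RP%04d-%03d", 1990L + sample(9L, 1L),
                              sample(999L, 1L))))
        core_uris[j] <- core_uri
      }
      for (s in seq_len(spec$slides_per_block)) {
        slide_no <- slide_no + 1L
        slide_id <- sprintf("slide%03d", slide_no)
        slide_uri <- paste0(nsmap$base, "#", slide_id)
        m <- add_node(m, "slide", slide_uri)
        edge(blk_uri, "includes_slide", slide_uri)
        for (j in seq_along(locs)) {
          sc_id <- paste0(slide_id, "-", locs[j])
          sc_uri <- paste0(nsmap$base, "#", sc_id)
          m <- add_node(m, "core_on_slide", sc_uri,
                        annotations = list(location = locs[j]))
          edge(slide_uri, "slide_includes_core", sc_uri)
          edge(sc_uri, "derived_from_core", core_uris[j])
        }
      }
    }
    add_edges_bulk(m, es, ep, eo)
  })
}

xml_id_of <- function(u, base) {
  basehash <- paste0(base, "#")
  if (startsWith(u, basehash)) substr(u, nchar(basehash) + 1L, nchar(u))
  else utils::URLdecode(sub("^.*/", "", u))
}

ann_value <- function(node, key) {
  v <- node$annotations[[key]]
  if (is.null(v) || !length(v)) NA_character_ else unclass(v[[1]])
}

#' Render a model as dialect XML
#'
#' Produces a document valid against the conversion dialect such that
#' `convert_tma_xml(render_xml(m), cfg)` is isomorphic to `to_graph(m)`.
#'
#' @param model A `tma_model` shaped like [generate_model()] output (one tma
#'   node; hierarchy edges present).
#' @return A character string (the XML document).
#' @export
render_xml <- function(model) {
  stopifnot(inherits(model, "tma_model"))
  base <- model$nsmap$base
  ed <- model$edges
  cls <- vapply(model$nodes, `[[`, character(1), "schema_class")
  tmas <- names(cls)[cls == "tma"]
  if (length(tmas) != 1L) stop("render error: model must have exactly one tma",
                               call. = FALSE)
  esc <- xml_escape_attr
  ann_elems <- function(node, skip, indent) {
    out <- character()
    for (k in names(node$annotations)) {
      if (k %in% skip) next
      tag <- if (grepl("[#/]", k)) next else k  # dialect carries bare tokens only
      for (v in node$annotations[[k]]) {
        out <- c(out, sprintf("%s<%s>%s</%s>", indent, tag,
                              xml_escape_text(unclass(v)), tag))
      }
    }
    out
  }
  core_xml <- function(u, indent, kind) {
    node <- model$nodes[[u]]
    at <- sprintf(" identifier=\"%s\"", esc(xml_id_of(u, base)))
    loc <- ann_value(node, "location")
    if (!is.na(loc)) at <- paste0(at, sprintf(" location=\"%s\"", esc(loc)))
    ds <- ann_value(node, "drill_site")
    if (!is.na(ds)) at <- paste0(at, sprintf(" drill_site=\"%s\"", esc(ds)))
    skip <- c("location", "drill_site")
    if (kind == "in_block") {
      donor <- ed$o[ed$s == u & ed$p == "donor_block"]
      if (length(donor)) at <- paste0(at, sprintf(" donor_block=\"%s\"",
                                                  esc(donor[1])))
      dg <- node$annotations[["diagnosis"]]
      if (!is.null(dg) && length(dg) && is_iri_value(dg[[1]])) {
        at <- paste0(at, sprintf(" diagnosis_term=\"%s\"", esc(unclass(dg[[1]]))))
        skip <- c(skip, "diagnosis")
      }
    }
    body <- ann_elems(node, skip, paste0(indent, "  "))
    if (length(body)) {
      c(sprintf("%s<core%s>", indent, at), body, sprintf("%s</core>", indent))
    } else {
      sprintf("%s<core%s/>", indent, at)
    }
  }
  tma_uri <- tmas[1]
  tnode <- model$nodes[[tma_uri]]
  at <- sprintf(" identifier=\"%s\"", esc(xml_id_of(tma_uri, base)))
  title <- ann_value(tnode, paste0(NS_DC, "title"))
  if (!is.na(title)) at <- paste0(at, sprintf(" title=\"%s\"", esc(title)))
  creator <- ann_value(tnode, paste0(NS_DC, "creator"))
  if (!is.na(creator)) at <- paste0(at, sprintf(" creator=\"%s\"", esc(creator)))
  repo <- ann_value(tnode, "repository")
  if (!is.na(repo)) at <- paste0(at, sprintf(" repository=\"%s\"", esc(repo)))
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           sprintf("<tma%s>", at),
           ann_elems(tnode, "repository", "  "))
  for (blk in ed$o[ed$s == tma_uri & ed$p == "includes_block"]) {
    bnode <- model$nodes[[blk]]
    out <- c(out, sprintf("  <block identifier=\"%s\">",
                          esc(xml_id_of(blk, base))),
             ann_elems(bnode, character(), "    "))
    for (sl in ed$o[ed$s == blk & ed$p == "includes_slide"]) {
      out <- c(out, sprintf("    <slide identifier=\"%s\">",
                            esc(xml_id_of(sl, base))),
               ann_elems(model$nodes[[sl]], character(), "      "))
      for (sc in ed$o[ed$s == sl & ed$p == "slide_includes_core"]) {
        out <- c(out, core_xml(sc, "      ", "on_slide"))
      }
      out <- c(out, "    </slide>")
    }
    for (c_ib in ed$o[ed$s == blk & ed$p == "block_includes_core"]) {
      out <- c(out, core_xml(c_ib, "    ", "in_block"))
    }
    out <- c(out, "  </block>")
  }
  out <- c(out, "</tma>", "")
  paste(out, collapse = "\n")
}

#' Inject a single seeded rule violation into a valid graph
#'
#' Produces exactly one corruption of the named kind: `E1` drops a typing
#' triple, `E2` rewires an edge to a wrong-class subject, `E3` retargets an
#' edge to a wrong-class internal object, `E4` adds a dangling fragment
#' reference, `E5` retypes a node with an abstract class.
#'
#' @param graph A valid `tma_graph`.
#' @param rule_id One of `"E1"`-`"E5"`.
#' @param seed Integer seed for the corruption site.
#' @param vocab A `tma_vocabulary`.
#' @return The mutated graph.
#' @export
mutate_graph <- function(graph, rule_id, seed = 1L, vocab = build_schema()) {
  stopifnot(inherits(graph, "tma_graph"),
            rule_id %in% c("E1", "E2", "E3", "E4", "E5"))
  ns <- vocab$namespace
  base <- graph$nsmap$base
  df <- canonical_triples(graph)
  keys <- triple_key(df)
  tok <- ifelse(startsWith(df$p, ns),
                substr(df$p, nchar(ns) + 1L, nchar(df$p)), NA_character_)
  is_obj <- !is.na(tok) & tok %in% object_properties(vocab) & !df$o_lit
  ty <- typing_table(df, vocab)
  typemap <- stats::setNames(ty$cls[!duplicated(ty$s)], ty$s[!duplicated(ty$s)])
  pick <- function(idx) if (length(idx) == 1L) idx else sample(idx, 1L)
  fail <- function() stop(sprintf(
    "mutation error: graph too small to host a %s mutation", rule_id),
    call. = FALSE)
  with_seed(seed, {
    if (rule_id == "E1") {
      cand <- which(df$p == RDF_TYPE & df$s %in% df$s[is_obj])
      if (!length(cand)) fail()
      # drop every typing triple of the chosen subject so no type remains
      victim <- df$s[pick(cand)]
      graph$triples <- graph$triples[
        !(graph$triples$p == RDF_TYPE & graph$triples$s == victim), ,
        drop = FALSE]
    } else if (rule_id == "E2") {
      cand <- integer()
      for (i in which(is_obj)) {
        dom <- vocab_property(vocab, tok[i])$domain
        if (any(typemap != dom & names(typemap) != df$s[i])) {
          cand <- c(cand, i)
        }
      }
      if (!length(cand)) fail()
      i <- pick(cand)
      dom <- vocab_property(vocab, tok[i])$domain
      subs <- names(typemap)[typemap != dom]
      if (!length(subs)) fail()
      subs <- subs[!(paste(subs, df$p[i], df$o[i], FALSE, sep = "\r") %in% keys)]
      if (!length(subs)) fail()
      s2 <- if (length(subs) == 1L) subs else sample(subs, 1L)
      hit <- which(triple_key(graph$triples) == keys[i])
      graph$triples$s[hit] <- s2
    } else if (rule_id == "E3") {
      cand <- integer()
      for (i in which(is_obj)) {
        rng <- vocab_property(vocab, tok[i])$range
        if (rng == "external") next
        if (!is.na(base) && is_internal(df$o[i], base)) cand <- c(cand, i)
      }
      if (!length(cand)) fail()
      i <- pick(cand)
      rng <- vocab_property(vocab, tok[i])$range
      objs <- names(typemap)[typemap != rng & is_internal(names(typemap), base)]
      if (!length(objs)) fail()
      objs <- objs[!(paste(df$s[i], df$p[i], objs, FALSE, sep = "\r") %in% keys)]
      if (!length(objs)) fail()
      o2 <- if (length(objs) == 1L) objs else sample(objs, 1L)
      hit <- which(triple_key(graph$triples) == keys[i])
      graph$triples$o[hit] <- o2
    } else if (rule_id == "E4") {
      if (is.na(base)) fail()
      # pick a typed subject and a property whose domain matches its class
      cand <- names(typemap)[typemap %in%
                               vocab$properties$domain[vocab$properties$kind ==
                                                         "object"]]
      if (!length(cand)) fail()
      s <- if (length(cand) == 1L) cand else sample(cand, 1L)
      props <- object_properties(vocab)
      props <- props[vapply(props, function(p)
        vocab_property(vocab, p)$domain == typemap[[s]], logical(1))]
      p <- if (length(props) == 1L) props else sample(props, 1L)
      ghost <- paste0(base, "#ghost", sample(1000L, 1L))
      graph <- add_triples(graph, s, paste0(ns, p), ghost)
    } else if (rule_id == "E5") {
      cand <- which(df$p == RDF_TYPE & !df$o_lit & startsWith(df$o, ns))
      if (!length(cand)) fail()
      i <- pick(cand)
      abs_cls <- sample(abstract_classes(vocab), 1L)
      hit <- which(triple_key(graph$triples) == keys[i])
      graph$triples$o[hit] <- paste0(ns, abs_cls)
    }
    graph$triples <- graph$triples[!duplicated(triple_key(graph$triples)), ,
                                   drop = FALSE]
    rownames(graph$triples) <- NULL
    graph
  })
}
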