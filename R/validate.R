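# Rule-based checking of instance graphs against the vocabulary, plus the one
# piece of inference the schema calls for: materializing paired inverse
# object properties.
#
# Rule registry
#   E1  subject of a vocabulary object property has no vocabulary typing
#   E2  domain violation on a vocabulary object property
#   E3  range violation (object internal to the document and typed)
#   E4  dangling internal fragment reference (referenced, no statements)
#   E5  node typed with an abstract class
#   W1  owl:Class used as typing predicate (accepted, normalized to rdf:type)
#   W2  location value not in letter+digits grid form ("D4")
#   W3  drill_site value not in "integer,integer" form ("78,90")
#   W4  datatype property used with the opposite value shape from the
#       documented conventions (diagnosis/clinical_annotation take resources;
#       repository/location/drill_site take literals)
#   W5  external reference (informational)
#
# Structural violations are errors; stylistic/usage issues are warnings, since
# the datatype-property conventions are conventions, not constraints. External
# IRIs are never errors: the instance documents simulate the existence of
# data files at those addresses.

RULE_REGISTRY <- c("E1", "E2", "E3", "E4", "E5", "W1", "W2", "W3", "W4", "W5")

W4_LITERAL_PROPS <- c("repository", "location", "drill_site")
W4_RESOURCE_PROPS <- c("diagnosis", "clinical_annotation")

empty_findings <- function() {
  data.frame(rule_id = character(), severity = character(),
             node = character(), message = character(), stringsAsFactors = FALSE)
}

new_finding <- function(rule_id, severity, node, message) {
  data.frame(rule_id = rule_id, severity = severity, node = node,
             message = message, stringsAsFactors = FALSE)
}

#' Normalize owl:Class typing statements
#'
#' The shorthand of printing `owl:Class` in predicate position is accepted on
#' input and rewritten to `rdf:type`; [validate()] reports each occurrence as
#' a `W1` warning.
#'
#' @param graph A `tma_graph`.
#' @return The normalized graph.
#' @export
normalize_typing <- function(graph) {
  hit <- graph$triples$p == OWL_CLASS & !graph$triples$o_lit
  if (any(hit)) {
    graph$triples$p[hit] <- RDF_TYPE
    graph$triples <- graph$triples[!duplicated(triple_key(graph$triples)), ,
                                   drop = FALSE]
    rownames(graph$triples) <- NULL
  }
  graph
}

# node -> first (canonical order) vocabulary class, over normalized typing
typing_table <- function(df, vocab) {
  ns <- vocab$namespace
  ty <- df[df$p == RDF_TYPE & !df$o_lit & startsWith(df$o, ns), , drop = FALSE]
  ty$cls <- substr(ty$o, nchar(ns) + 1L, nchar(ty$o))
  ty <- ty[ty$cls %in% vocab$classes$local_name, , drop = FALSE]
  ty
}

#' Validate an instance graph against the vocabulary
#'
#' Applies the rule registry (errors `E1`-`E5`, warnings `W1`-`W5`; see the
#' package vignette) without mutating the graph. External references are
#' reported informationally, never as errors.
#'
#' @param graph A `tma_graph`.
#' @param vocab A `tma_vocabulary`.
#' @param base Document base IRI; fragments of it count as internal. Defaults
#'   to the graph's namespace map base.
#' @return A `tma_validation_report`: list with `findings` (data.frame:
#'   `rule_id`, `severity`, `node`, `message`) and `valid` (no error-severity
#'   findings).
#' @export
validate <- function(graph, vocab = build_schema(), base = graph$nsmap$base) {
  stopifnot(inherits(graph, "tma_graph"))
  findings <- list()
  add <- function(rule_id, severity, node, message) {
    findings[[length(findings) + 1L]] <<- new_finding(rule_id, severity,
                                                      node, message)
  }
  raw <- graph$triples
  w1 <- raw[raw$p == OWL_CLASS & !raw$o_lit, , drop = FALSE]
  for (s in w1$s) {
    add("W1", "warning", s, "owl:Class used as typing predicate; read as rdf:type")
  }
  df <- canonical_triples(normalize_typing(graph))
  ns <- vocab$namespace
  ty <- typing_table(df, vocab)
  first_type <- ty[!duplicated(ty$s), , drop = FALSE]
  typemap <- stats::setNames(first_type$cls, first_type$s)
  multi <- unique(ty$s[duplicated(ty$s)])
  for (s in multi) {
    add("W1", "warning", s,
        sprintf("node has multiple vocabulary types; using '%s'", typemap[[s]]))
  }
  for (i in which(first_type$cls %in% abstract_classes(vocab))) {
    add("E5", "error", first_type$s[i],
        sprintf("node typed with abstract class '%s'", first_type$cls[i]))
  }
  abs_typed <- ty$s[ty$cls %in% abstract_classes(vocab)]
  for (s in setdiff(abs_typed, first_type$s[first_type$cls %in%
                                            abstract_classes(vocab)])) {
    add("E5", "error", s, "node typed with abstract class")
  }
  obj_props <- object_properties(vocab)
  prop_tok <- ifelse(startsWith(df$p, ns),
                     substr(df$p, nchar(ns) + 1L, nchar(df$p)), NA_character_)
  is_obj <- !is.na(prop_tok) & prop_tok %in% obj_props
  internal <- function(x) !is.na(base) & is_internal(x, base)
  subjects_with_statements <- unique(df$s)
  for (i in which(is_obj)) {
    p <- prop_tok[i]
    prow <- vocab_property(vocab, p)
    s <- df$s[i]; o <- df$o[i]
    scls <- typemap[s]
    if (is.na(scls)) {
      add("E1", "error", s,
          sprintf("subject of object property '%s' has no vocabulary type", p))
    } else if (!(scls %in% abstract_classes(vocab)) && scls != prow$domain) {
      add("E2", "error", s,
          sprintf("domain violation: '%s' requires a %s subject, found %s",
                  p, prow$domain, scls))
    }
    if (df$o_lit[i]) {
      add("E3", "error", s,
          sprintf("range violation: object of '%s' is a literal", p))
    } else if (internal(o)) {
      ocls <- typemap[o]
      if (!is.na(ocls) && prow$range != "external" &&
          !(ocls %in% abstract_classes(vocab)) && ocls != prow$range) {
        add("E3", "error", o,
            sprintf("range violation: '%s' requires a %s object, found %s",
                    p, prow$range, ocls))
      }
    } else {
      add("W5", "warning", o,
          sprintf("external reference via '%s' (target simulated, not fetched)", p))
    }
  }
  # dangling internal fragment references
  refs <- unique(df$o[!df$o_lit])
  for (o in refs) {
    if (internal(o) && !is.na(base) && o != base &&
        !(o %in% subjects_with_statements)) {
      add("E4", "error", o, "dangling internal fragment reference")
    }
  }
  # annotation-value conventions
  is_ann <- !is.na(prop_tok) & prop_tok %in% annotation_properties(vocab)
  for (i in which(is_ann)) {
    p <- prop_tok[i]
    if (p == "location" && df$o_lit[i] &&
        !grepl("^[A-Za-z][0-9]+$", df$o[i])) {
      add("W2", "warning", df$s[i],
          sprintf("location '%s' is not in grid form like 'D4'", df$o[i]))
    }
    if (p == "drill_site" && df$o_lit[i] &&
        !grepl("^[0-9]+,[0-9]+$", df$o[i])) {
      add("W3", "warning", df$s[i],
          sprintf("drill_site '%s' is not in 'x,y' integer form", df$o[i]))
    }
    if (p %in% W4_LITERAL_PROPS && !df$o_lit[i]) {
      add("W4", "warning", df$s[i],
          sprintf("'%s' conventionally takes a literal value", p))
    }
    if (p %in% W4_RESOURCE_PROPS && df$o_lit[i]) {
      add("W4", "warning", df$s[i],
          sprintf("'%s' conventionally points to a resource", p))
    }
  }
  findings <- if (length(findings)) do.call(rbind, findings) else empty_findings()
  rownames(findings) <- NULL
  structure(list(findings = findings,
                 valid = !any(findings$severity == "error")),
            class = "tma_validation_report")
}

format_findings <- function(findings) {
  if (!nrow(findings)) return(character())
  sprintf("[%s/%s] %s: %s", findings$rule_id, findings$severity,
          findings$node, findings$message)
}

#' @export
print.tma_validation_report <- function(x, ...) {
  cat(sprintf("<tma_validation_report> valid: %s (%d error(s), %d warning(s))\n",
              x$valid, sum(x$findings$severity == "error"),
              sum(x$findings$severity == "warning")))
  for (line in format_findings(x$findings)) cat(" ", line, "\n")
  invisible(x)
}

#' Render a validation report as JSON
#' @param report A `tma_validation_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  jsonlite::toJSON(list(valid = report$valid, findings = report$findings),
                   auto_unbox = TRUE, pretty = TRUE)
}

paired_props <- function(vocab) {
  pr <- vocab$properties
  pr[pr$kind == "object" & !is.na(pr$inverse), , drop = FALSE]
}

#' Materialize paired inverse properties
#'
#' For every statement `(a p b)` whose property has a paired inverse `q`, the
#' output additionally contains `(b q a)`. Nothing else is added, input
#' triples are retained, and the operation is idempotent.
#'
#' @param graph A `tma_graph`.
#' @param vocab A `tma_vocabulary`.
#' @return The materialized graph.
#' @export
materialize_inverses <- function(graph, vocab = build_schema()) {
  ns <- vocab$namespace
  pp <- paired_props(vocab)
  inv <- stats::setNames(pp$inverse, pp$local_name)
  df <- graph$triples
  tok <- ifelse(startsWith(df$p, ns),
                substr(df$p, nchar(ns) + 1L, nchar(df$p)), NA_character_)
  hit <- !is.na(tok) & tok %in% names(inv) & !df$o_lit
  if (any(hit)) {
    graph <- add_triples(graph, df$o[hit], paste0(ns, inv[tok[hit]]), df$s[hit])
  }
  graph
}

#' Strip one direction of each inverse pair
#'
#' Keeps only the chosen direction (`top_down`: container-to-part edges such
#' as `includes_block`; `bottom_up`: part-to-parent edges such as
#' `cut_from_block`) so that [materialize_inverses()] recovers the full
#' materialized graph. The input must already be inverse-consistent.
#'
#' @param graph A materialized `tma_graph`.
#' @param vocab A `tma_vocabulary`.
#' @param keep `"top_down"` or `"bottom_up"`.
#' @return The stripped graph.
#' @export
strip_inverses <- function(graph, vocab = build_schema(),
                           keep = c("top_down", "bottom_up")) {
  keep <- match.arg(keep)
  ns <- vocab$namespace
  pp <- paired_props(vocab)
  df <- graph$triples
  tok <- ifelse(startsWith(df$p, ns),
                substr(df$p, nchar(ns) + 1L, nchar(df$p)), NA_character_)
  paired_hit <- !is.na(tok) & tok %in% pp$local_name & !df$o_lit
  # consistency: every paired statement must carry its inverse
  if (any(paired_hit)) {
    keys <- triple_key(df)
    inv <- stats::setNames(pp$inverse, pp$local_name)
    want <- paste(df$o[paired_hit], paste0(ns, inv[tok[paired_hit]]),
                  df$s[paired_hit], FALSE, sep = "\r")
    if (!all(want %in% keys)) {
      stop("strip error: graph is not inverse-materialized", call. = FALSE)
    }
  }
  dirmap <- stats::setNames(pp$direction, pp$local_name)
  drop <- paired_hit & dirmap[tok] != keep
  drop[is.na(drop)] <- FALSE
  graph$triples <- df[!drop, , drop = FALSE]
  rownames(graph$triples) <- NULL
  graph
}
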