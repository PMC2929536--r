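# Well-known namespaces. The dc namespace deliberately ends in "#": that is the
# expansion the TMA shorthand convention prescribes for dc:title, and namespace
# strings are configuration, so users may rebind dc to the slash form.
NS_TMA  <- "http://bioontology.org/ontologies/tma-minimal#"
NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL  <- "http://www.w3.org/2002/07/owl#"
NS_DC   <- "http://purl.org/dc/elements/1.1#"

RDF_TYPE  <- paste0(NS_RDF, "type")
OWL_CLASS <- paste0(NS_OWL, "Class")

#' Namespace map
#'
#' A prefix-to-namespace table plus an optional document base IRI, used to
#' expand `prefix:local` and `#fragment` shorthands and to compact absolute
#' IRIs for serialization.
#'
#' @param prefixes Named character vector mapping prefix tokens to namespace
#'   IRIs. Prefix tokens must be unique.
#' @param base Document base IRI (absolute), or `NA`. Required whenever
#'   `#fragment` shorthand is used.
#' @return An object of class `tma_nsmap`.
#' @examples
#' ns <- tma_nsmap(base = "http://www.the_url_here.org/tma_example1.rdf")
#' expand_shorthand("#slide058", ns)
#' @export
tma_nsmap <- function(prefixes = character(), base = NA_character_) {
  prefixes <- unlist(prefixes)
  if (is.null(prefixes)) prefixes <- character()
  storage.mode(prefixes) <- "character"
  if (anyDuplicated(names(prefixes))) {
    stop("duplicate prefix tokens in namespace map", call. = FALSE)
  }
  structure(list(prefixes = prefixes, base = as.character(base)[1]),
            class = "tma_nsmap")
}

#' Default namespace map for TMA documents
#'
#' Binds the `tma`, `rdf`, `rdfs`, `owl` and `dc` prefixes to their
#' conventional namespaces.
#'
#' @inheritParams tma_nsmap
#' @return A `tma_nsmap`.
#' @export
default_nsmap <- function(base = NA_character_) {
  tma_nsmap(c(tma = NS_TMA, rdf = NS_RDF, rdfs = NS_RDFS,
              owl = NS_OWL, dc = NS_DC), base = base)
}

#' @export
print.tma_nsmap <- function(x, ...) {
  cat("<tma_nsmap>\n")
  if (!is.na(x$base)) cat("  base:", x$base, "\n")
  for (p in names(x$prefixes)) cat(sprintf("  %s: %s\n", p, x$prefixes[[p]]))
  invisible(x)
}
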