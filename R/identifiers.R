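# Linked Data identifier handling: stable URI minting under an HTTP authority,
# CURIE/fragment expansion against a namespace map, and compaction back to
# shorthand for readable serializations.

SCHEME_RE <- "^[A-Za-z][A-Za-z0-9+.-]*:"

is_absolute_iri <- function(x) grepl(paste0(SCHEME_RE, "//"), x) | grepl("^urn:", x)

#' Percent-encode a URI key
#'
#' Encodes every character outside the RFC 3986 unreserved set
#' (`A-Z a-z 0-9 - . _ ~`) as UTF-8 percent triplets with uppercase hex.
#' An existing `%hh` triplet (percent followed by two hex digits) is passed
#' through unchanged so already-encoded keys are not double-encoded.
#'
#' @param key Character scalar to encode.
#' @return The encoded string.
#' @examples
#' pct_encode("RP 2008/325")
#' pct_encode("RP%202008")  # not double-encoded
#' @export
pct_encode <- function(key) {
  stopifnot(is.character(key), length(key) == 1L, !is.na(key))
  # tokenize: keep %hh intact, everything else char by char
  m <- gregexpr("%[0-9A-Fa-f]{2}|.", key, perl = TRUE)
  toks <- regmatches(key, m)[[1]]
  enc1 <- function(tok) {
    if (nchar(tok) == 3L && substr(tok, 1, 1) == "%") return(tok)
    if (grepl("^[A-Za-z0-9._~-]$", tok)) return(tok)
    paste(sprintf("%%%02X", as.integer(charToRaw(tok))), collapse = "")
  }
  paste(vapply(toks, enc1, character(1)), collapse = "")
}

#' URI minting policy
#'
#' Captures the Linked Data conventions for a publishing institution: an HTTP
#' namespace under the publisher's control (scheme + authority) and, per schema
#' class, the collection path under which resource keys are minted. Keys should
#' be domain-meaningful identifiers (an accession number, a repository id), not
#' internal database keys.
#'
#' @param authority Hostname owning the namespace, e.g. `"www.institutionXYZ.org"`.
#' @param scheme URI scheme, default `"http"`.
#' @param path_templates Named list mapping schema class tokens to a character
#'   vector of path segments (e.g. `list(tma = "tma", block = "block")`).
#' @return An object of class `tma_uri_policy`.
#' @export
uri_policy <- function(authority,
                       scheme = "http",
                       path_templates = list(tma = "tma", block = "block")) {
  if (!is.character(authority) || length(authority) != 1L || !nzchar(authority)) {
    stop("authority must be a non-empty hostname", call. = FALSE)
  }
  for (tpl in path_templates) {
    if (any(!nzchar(tpl))) stop("path templates must not contain empty segments",
                                call. = FALSE)
  }
  structure(list(scheme = scheme, authority = authority,
                 path_templates = path_templates),
            class = "tma_uri_policy")
}

#' Mint a stable resource URI
#'
#' Deterministically constructs `scheme://authority/path.../key` with the key
#' percent-encoded. The same policy, path and key always yield the same URI,
#' so identifiers stay stable and persistent once published.
#'
#' @param policy A [uri_policy()].
#' @param path Character vector of collection path segments (may be empty).
#' @param key Non-empty resource key; percent-encoded on insertion.
#' @return Absolute URI string.
#' @examples
#' p <- uri_policy("www.institutionXYZ.org")
#' mint_uri(p, c("tma", "rdf"), "123456")
#' @export
mint_uri <- function(policy, path = character(), key) {
  stopifnot(inherits(policy, "tma_uri_policy"))
  if (!is.character(key) || length(key) != 1L || is.na(key) || !nzchar(key)) {
    stop("minting error: key must be a non-empty string", call. = FALSE)
  }
  enc <- pct_encode(key)
  if (!nzchar(enc)) stop("minting error: key encodes to empty", call. = FALSE)
  if (length(path) && any(!nzchar(path))) {
    stop("minting error: empty path segment", call. = FALSE)
  }
  segs <- c(path, enc)
  paste0(policy$scheme, "://", policy$authority, "/", paste(segs, collapse = "/"))
}

#' Mint a URI for a schema class using the policy's path template
#'
#' @inheritParams mint_uri
#' @param schema_class Class token with an entry in the policy's
#'   `path_templates`.
#' @return Absolute URI string.
#' @export
mint_class_uri <- function(policy, schema_class, key) {
  tpl <- policy$path_templates[[schema_class]]
  if (is.null(tpl)) {
    stop(sprintf("minting error: no path template for class '%s'", schema_class),
         call. = FALSE)
  }
  mint_uri(policy, tpl, key)
}

#' Expand a shorthand identifier to an absolute IRI
#'
#' Accepts `#fragment` (joined to the document base with `#`), `prefix:local`
#' (namespace concatenation, exactly as the shorthand convention prescribes),
#' or an absolute IRI (returned unchanged).
#'
#' @param shorthand The shorthand string.
#' @param nsmap A [tma_nsmap()] supplying prefixes and the base IRI.
#' @return Absolute IRI string.
#' @examples
#' ns <- default_nsmap(base = "http://www.the_url_here.org/tma_example1.rdf")
#' expand_shorthand("#slide058", ns)
#' expand_shorthand("tma:block", ns)
#' expand_shorthand("dc:title", ns)
#' @export
expand_shorthand <- function(shorthand, nsmap) {
  stopifnot(is.character(shorthand), length(shorthand) == 1L)
  x <- shorthand
  if (is_absolute_iri(x)) return(x)
  if (startsWith(x, "#")) {
    if (is.na(nsmap$base)) {
      stop("expansion error: '#' shorthand used without a base IRI", call. = FALSE)
    }
    return(paste0(nsmap$base, x))
  }
  if (grepl(":", x, fixed = TRUE)) {
    pfx <- sub(":.*$", "", x)
    local <- sub("^[^:]*:", "", x)
    if (!(pfx %in% names(nsmap$prefixes))) {
      stop(sprintf("expansion error: unknown prefix '%s'", pfx), call. = FALSE)
    }
    return(paste0(nsmap$prefixes[[pfx]], local))
  }
  stop(sprintf("expansion error: '%s' is not a fragment, CURIE, or absolute IRI", x),
       call. = FALSE)
}

valid_local_part <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", x)

#' Compact an absolute IRI to shorthand
#'
#' The longest matching declared namespace wins; a match on the document base
#' yields `#fragment` form. IRIs matching nothing (or whose local part is not a
#' clean token) are returned unchanged, so `expand_shorthand(compact_iri(x))`
#' is always `x`.
#'
#' @param iri Absolute IRI string.
#' @param nsmap A [tma_nsmap()].
#' @return Shorthand or the unchanged IRI.
#' @export
compact_iri <- function(iri, nsmap) {
  stopifnot(is.character(iri), length(iri) == 1L)
  best <- NULL
  best_len <- -1L
  for (p in names(nsmap$prefixes)) {
    ns <- nsmap$prefixes[[p]]
    if (startsWith(iri, ns) && nchar(ns) > best_len) {
      local <- substr(iri, nchar(ns) + 1L, nchar(iri))
      if (valid_local_part(local)) {
        best <- paste0(p, ":", local)
        best_len <- nchar(ns)
      }
    }
  }
  if (!is.na(nsmap$base)) {
    basehash <- paste0(nsmap$base, "#")
    if (startsWith(iri, basehash) && nchar(basehash) > best_len) {
      frag <- substr(iri, nchar(basehash) + 1L, nchar(iri))
      if (nzchar(frag)) best <- paste0("#", frag)
    }
  }
  if (is.null(best)) iri else best
}

#' Is an IRI internal to a document?
#'
#' True when the IRI is the document base itself or a `#` fragment of it.
#' Internal resources are described within the document; everything else is an
#' external reference whose target is simulated, never fetched.
#'
#' @param iri IRI to test.
#' @param base Document base IRI.
#' @return Logical scalar.
#' @export
is_internal <- function(iri, base) {
  if (is.na(base)) return(FALSE)
  iri == base | startsWith(iri, paste0(base, "#"))
}
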