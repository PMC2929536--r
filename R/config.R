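# Configuration file support (YAML or JSON): namespace prefixes, document
# base, URI policy, and synthetic-fixture settings. Unknown keys are rejected
# so typos fail loudly.

CONFIG_KEYS <- c("prefixes", "base", "authority", "scheme", "path_templates",
                 "direction", "synth", "log_level")
SYNTH_KEYS <- c("seed", "n_blocks", "grid_rows", "grid_cols",
                "slides_per_block", "fill_rate", "diagnosis_pool",
                "annotation_noise")

#' Read a tmaowl configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file with any of the sections:
#'   `prefixes` (map), `base`, `authority`, `scheme`, `path_templates` (map of
#'   class to path segments), `direction`, `synth` (a [synth_spec()] field
#'   map), `log_level`.
#' @return A list with classed components: `nsmap` ([tma_nsmap()]), `policy`
#'   ([uri_policy()] or `NULL`), `direction`, `synth` ([synth_spec()] or
#'   `NULL`), `log_level`.
#' @export
read_tma_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config error: file '%s' not found", path), call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown)) {
    stop(sprintf("config error: unknown key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  prefixes <- default_nsmap()$prefixes
  if (!is.null(raw$prefixes)) {
    user <- unlist(raw$prefixes)
    prefixes[names(user)] <- user
  }
  nsmap <- tma_nsmap(prefixes,
                     base = if (is.null(raw$base)) NA_character_ else raw$base)
  policy <- NULL
  if (!is.null(raw$authority)) {
    tpl <- if (is.null(raw$path_templates)) list(tma = "tma", block = "block")
           else lapply(raw$path_templates, as.character)
    policy <- uri_policy(raw$authority,
                         scheme = if (is.null(raw$scheme)) "http" else raw$scheme,
                         path_templates = tpl)
  }
  synth <- NULL
  if (!is.null(raw$synth)) {
    unknown <- setdiff(names(raw$synth), SYNTH_KEYS)
    if (length(unknown)) {
      stop(sprintf("config error: unknown synth key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    synth <- do.call(synth_spec, raw$synth)
  }
  list(nsmap = nsmap, policy = policy,
       direction = if (is.null(raw$direction)) "top_down" else raw$direction,
       synth = synth,
       log_level = if (is.null(raw$log_level)) "info" else raw$log_level)
}
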