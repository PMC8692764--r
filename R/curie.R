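OBO_PURL_BASE <- "http://purl.obolibrary.org/obo/"

#' Convert between CURIEs and OBO PURLs
#'
#' OBO Foundry terms have two interconvertible spellings: a compact identifier
#' (CURIE) such as `"ENVO:01000253"` and a resolvable persistent URL obtained
#' by replacing the colon with an underscore and prefixing the OBO PURL base,
#' `"http://purl.obolibrary.org/obo/ENVO_01000253"`. The mapping is bijective
#' for OBO-namespace identifiers; non-OBO IRIs are rejected rather than
#' guessed at.
#'
#' @param curie Character vector of compact identifiers, `PREFIX:LOCALID`.
#' @param purl Character vector of OBO persistent URLs.
#' @return The converted character vector.
#' @examples
#' curie_to_purl("ENVO:01000253")
#' purl_to_curie("http://purl.obolibrary.org/obo/UO_0010004")
#' @export
curie_to_purl <- function(curie) {
  ok <- grepl("^[A-Za-z][A-Za-z0-9.]*:[A-Za-z0-9_.-]+$", curie)
  if (!all(ok))
    stop_oceanpack("curie_format",
                   sprintf("malformed CURIE: %s", paste(curie[!ok], collapse = ", ")))
  paste0(OBO_PURL_BASE, sub(":", "_", curie, fixed = TRUE))
}

#' @rdname curie_to_purl
#' @export
purl_to_curie <- function(purl) {
  ok <- startsWith(purl, OBO_PURL_BASE)
  if (!all(ok))
    stop_oceanpack("unsupported_namespace",
                   sprintf("not an OBO PURL: %s", paste(purl[!ok], collapse = ", ")))
  local <- substring(purl, nchar(OBO_PURL_BASE) + 1L)
  bad <- !grepl("^[A-Za-z][A-Za-z0-9.]*_[A-Za-z0-9_.-]+$", local)
  if (any(bad))
    stop_oceanpack("curie_format",
                   sprintf("malformed OBO local id: %s", paste(local[bad], collapse = ", ")))
  sub("_", ":", local)
}

curie_prefix <- function(curie) sub(":.*$", "", curie)

#' Reference to an ontology term
#'
#' A lightweight value type pairing a CURIE with its PURL and (optionally) a
#' human-readable label. Either spelling may be supplied; the other is derived.
#'
#' @param id A CURIE (`"ENVO:3100022"`) or an OBO PURL.
#' @param label Optional label string.
#' @return An object of class `ontology_term_ref` with elements `curie`,
#'   `purl`, `label`.
#' @export
term_ref <- function(id, label = "") {
  if (is.null(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop_oceanpack("curie_format", "term id must be a non-empty string")
  curie <- if (startsWith(id, "http://") || startsWith(id, "https://"))
    purl_to_curie(id) else id
  structure(
    list(curie = curie, purl = curie_to_purl(curie), label = label %||% ""),
    class = "ontology_term_ref"
  )
}

#' @export
print.ontology_term_ref <- function(x, ...) {
  lab <- if (nzchar(x$label)) sprintf(" \"%s\"", x$label) else ""
  cat(sprintf("<term %s%s>\n", x$curie, lab))
  invisible(x)
}

#' @export
format.ontology_term_ref <- function(x, ...) x$curie
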