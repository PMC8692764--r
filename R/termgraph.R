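## Ontology term graph ---------------------------------------------------
##
## A deliberately small model of an OBO ontology fragment: terms with labels
## and is-a (subclass) parents only. Subsumption-aware attribute discovery
## needs nothing more than the transitive closure over is-a edges; other OBO
## relations (part-of, located-in) and OWL reasoning are out of scope. Term
## tables are flat TSVs exported from released ontologies, with the columns
## curie <TAB> label <TAB> parents (pipe-separated CURIEs).

new_term_graph <- function(terms, parents, dangling = character()) {
  structure(list(terms = terms, parents = parents, dangling = dangling),
            class = "term_graph")
}

#' Build a term graph from a (curie, label, parents) table
#'
#' @param rows A data frame with character columns `curie`, `label`,
#'   `parents` (pipe-separated parent CURIEs, empty for roots), or a path to
#'   a TSV with that header.
#' @return A `term_graph`. Parent CURIEs that are not themselves rows are
#'   kept but flagged as dangling (a warning of class
#'   `oceanpack_dangling_parent` is signalled).
#' @examples
#' g <- load_term_table(oceanpack_term_table())
#' resolve_term(g, "marine mesopelagic zone")
#' @export
load_term_table <- function(rows) {
  if (is.character(rows) && length(rows) == 1L) {
    rows <- utils::read.delim(rows, colClasses = "character",
                              na.strings = NULL, comment.char = "#",
                              quote = "", check.names = FALSE)
  }
  need <- c("curie", "label", "parents")
  if (!all(need %in% names(rows)))
    stop_oceanpack("schema",
                   sprintf("term table needs columns %s", paste(need, collapse = ", ")))
  if (nrow(rows) == 0L)
    stop_oceanpack("schema", "term table is empty")
  if (anyDuplicated(rows$curie))
    stop_oceanpack("duplicate_term",
                   sprintf("duplicate CURIE(s): %s",
                           paste(unique(rows$curie[duplicated(rows$curie)]),
                                 collapse = ", ")))
  parents <- lapply(strsplit(rows$parents, "|", fixed = TRUE),
                    function(p) p[nzchar(p)])
  names(parents) <- rows$curie
  terms <- data.frame(curie = rows$curie, label = rows$label,
                      prefix = curie_prefix(rows$curie),
                      stringsAsFactors = FALSE)
  dangling <- setdiff(unique(unlist(parents)), rows$curie)
  g <- new_term_graph(terms, parents, dangling)
  cyc <- find_cycle(g)
  if (!is.null(cyc))
    stop_oceanpack("cyclic_hierarchy",
                   sprintf("is-a hierarchy contains a cycle: %s",
                           paste(cyc, collapse = " -> ")))
  if (length(dangling))
    warn_oceanpack("dangling_parent",
                   sprintf("parent term(s) not in table: %s",
                           paste(dangling, collapse = ", ")))
  g
}

## Iterative DFS over is-a edges; returns one cycle as a CURIE path, or NULL.
find_cycle <- function(g) {
  color <- setNames(rep(0L, nrow(g$terms)), g$terms$curie) # 0 white 1 grey 2 black
  for (start in g$terms$curie) {
    if (color[[start]] != 0L) next
    stack <- list(list(node = start, i = 1L))
    path <- character()
    while (length(stack)) {
      top <- stack[[length(stack)]]
      node <- top$node
      if (top$i == 1L) {
        color[[node]] <- 1L
        path <- c(path, node)
      }
      kids <- intersect(g$parents[[node]], g$terms$curie)
      if (top$i <= length(kids)) {
        stack[[length(stack)]]$i <- top$i + 1L
        kid <- kids[[top$i]]
        if (color[[kid]] == 1L)
          return(c(path[which(path == kid):length(path)], kid))
        if (color[[kid]] == 0L)
          stack[[length(stack) + 1L]] <- list(node = kid, i = 1L)
      } else {
        color[[node]] <- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

assert_in_graph <- function(graph, curie) {
  if (!curie %in% graph$terms$curie)
    stop_oceanpack("unknown_term", sprintf("unknown term: %s", curie))
}

#' Ancestor and descendant closures
#'
#' Transitive (strict: a term is not its own ancestor) closure over is-a
#' edges. `descendants(g, x)` is the dual set `{y : x %in% ancestors(g, y)}`,
#' which is what a subsumption-aware attribute search expands a query term
#' into.
#'
#' @param graph A `term_graph`.
#' @param curie Term CURIE present in the graph.
#' @return Character vector of CURIEs (possibly empty), sorted.
#' @export
ancestors <- function(graph, curie) {
  assert_in_graph(graph, curie)
  seen <- character()
  frontier <- intersect(graph$parents[[curie]], graph$terms$curie)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      intersect(unique(unlist(graph$parents[frontier])), graph$terms$curie),
      seen)
  }
  sort(seen)
}

#' @rdname ancestors
#' @export
descendants <- function(graph, curie) {
  assert_in_graph(graph, curie)
  child_of <- function(nodes) {
    hit <- vapply(graph$terms$curie,
                  function(c) any(graph$parents[[c]] %in% nodes), logical(1))
    graph$terms$curie[hit]
  }
  seen <- character()
  frontier <- child_of(curie)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(child_of(frontier), seen)
  }
  sort(seen)
}

#' Resolve a CURIE or label to a term reference
#'
#' CURIE lookup is tried first, then exact case-insensitive label match. Two
#' terms sharing a label make the label ambiguous and raise an error listing
#' the candidates; no stemming or fuzzy matching is attempted, since a wrong
#' silent match is worse than a failed lookup.
#'
#' @param graph A `term_graph`.
#' @param query A CURIE or an exact label.
#' @return An `ontology_term_ref`.
#' @export
resolve_term <- function(graph, query) {
  i <- match(query, graph$terms$curie)
  if (is.na(i)) {
    hits <- which(tolower(graph$terms$label) == tolower(query))
    if (length(hits) > 1L)
      stop_oceanpack("ambiguous_label",
                     sprintf("label \"%s\" matches %d terms: %s", query,
                             length(hits),
                             paste(graph$terms$curie[hits], collapse = ", ")))
    if (length(hits) == 0L)
      stop_oceanpack("unknown_term", sprintf("no term matching \"%s\"", query))
    i <- hits
  }
  term_ref(graph$terms$curie[i], graph$terms$label[i])
}

#' @export
print.term_graph <- function(x, ...) {
  cat(sprintf("<term graph: %d term(s), %d prefix namespace(s)%s>\n",
              nrow(x$terms), length(unique(x$terms$prefix)),
              if (length(x$dangling))
                sprintf(", %d dangling parent(s)", length(x$dangling)) else ""))
  invisible(x)
}

#' Path to the bundled ontology term table
#'
#' A small TSV fragment of ENVO/UO/OBI/CHEBI/PATO/PMO terms covering marine
#' sample metadata: chemical concentration attributes, environmental
#' biome/feature/material context, climate zones, units and measurement
#' devices. One synthetic entry (`TEMP:0000001`, phosphate concentration) has
#' no released ENVO identifier and is marked as such in the file.
#'
#' @return File path of the bundled TSV.
#' @export
oceanpack_term_table <- function() {
  system.file("extdata", "terms.tsv", package = "oceanpack", mustWork = TRUE)
}

## -- concentration-term minting -----------------------------------------

PATO_CONCENTRATION <- "PATO:0000033"

#' Mint a chemical concentration term
#'
#' Compiles a (solute, material) pair into a new concentration term following
#' the dead-simple design pattern used for the ENVO chemical concentration
#' module: label `"concentration of <solute> in <material>"` and an
#' equivalence expression linking the concentration quality (PATO:0000033) to
#' the CHEBI solute and the ENVO environmental material. Minted terms get
#' provisional `TEMP:` identifiers; released ENVO numeric ids are never
#' fabricated.
#'
#' @param graph A `term_graph` resolving both inputs.
#' @param solute CURIE of a CHEBI chemical entity.
#' @param material CURIE of an ENVO environmental material.
#' @return A `minted_term`: list with `id`, `label`, `solute`, `material`,
#'   `quality` and the deterministic `equivalence` serialization.
#' @examples
#' g <- load_term_table(oceanpack_term_table())
#' mint_concentration_term(g, "CHEBI:18230", "ENVO:00002006")
#' @export
mint_concentration_term <- function(graph, solute, material) {
  if (curie_prefix(solute) != "CHEBI")
    stop_oceanpack("namespace",
                   sprintf("solute must be a CHEBI term, got %s", solute))
  sol <- resolve_term(graph, solute)
  mat <- resolve_term(graph, material)
  qual <- resolve_term(graph, PATO_CONCENTRATION)
  label <- sprintf("concentration of %s in %s", sol$label, mat$label)
  equivalence <- sprintf(
    "'%s' (%s) and inheres-in some ('%s' (%s) and part-of some '%s' (%s))",
    qual$label, qual$curie, sol$label, sol$curie, mat$label, mat$curie)
  structure(
    list(
      id = sprintf("TEMP:%s-%s", sub(":", "_", sol$curie), sub(":", "_", mat$curie)),
      label = label, solute = sol, material = mat, quality = qual,
      equivalence = equivalence),
    class = "minted_term"
  )
}

#' @export
print.minted_term <- function(x, ...) {
  cat(sprintf("<minted term %s>\n  label: %s\n  equivalence: %s\n",
              x$id, x$label, x$equivalence))
  invisible(x)
}
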