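## Unit registry ---------------------------------------------------------
##
## Conversions are affine maps (value * factor + offset) between UO unit
## terms. The registry is an undirected graph: a registered a -> b edge makes
## b -> a derivable by inversion, and chains compose along paths. Units fall
## into "dimension groups" (connected components); a conversion across
## groups is refused unless an explicit bridge assumption has been added —
## silent over-harmonization across incompatible unit systems is exactly
## what semantic unit annotation is meant to prevent.

#' Build a unit conversion registry
#'
#' @param rows Data frame with columns `from_curie`, `to_curie`, `factor`,
#'   `offset`, or path to a TSV with that header (default: the bundled
#'   registry covering molar concentrations, temperature and the
#'   micromole-per-kilogram group).
#' @return A `unit_registry`.
#' @examples
#' reg <- load_unit_registry()
#' convert_value(1, "UO:0000064", "UO:0000065", reg)   # micromolar -> nanomolar
#' @export
load_unit_registry <- function(rows = NULL) {
  if (is.null(rows))
    rows <- system.file("extdata", "unit_registry.tsv", package = "oceanpack",
                        mustWork = TRUE)
  if (is.character(rows) && length(rows) == 1L)
    rows <- utils::read.delim(rows, comment.char = "#", quote = "",
                              colClasses = c("character", "character",
                                             "numeric", "numeric"))
  need <- c("from_curie", "to_curie", "factor", "offset")
  if (!all(need %in% names(rows)))
    stop_oceanpack("schema",
                   sprintf("unit registry needs columns %s",
                           paste(need, collapse = ", ")))
  if (any(rows$factor == 0))
    stop_oceanpack("schema", "unit conversion factor must be non-zero")
  structure(list(edges = rows, assumptions = character()),
            class = "unit_registry")
}

registry_units <- function(registry)
  unique(c(registry$edges$from_curie, registry$edges$to_curie))

## BFS over the conversion graph composing affine transforms.
## Returns c(factor, offset) mapping `from` values into `to` values.
find_conversion <- function(registry, from, to) {
  units <- registry_units(registry)
  for (u in c(from, to))
    if (!u %in% units)
      stop_oceanpack("unknown_unit", sprintf("unit not registered: %s", u))
  if (from == to) return(c(factor = 1, offset = 0))
  ## transform[u] maps a value in `from` units to a value in u's units
  transform <- list()
  transform[[from]] <- c(1, 0)
  frontier <- from
  while (length(frontier)) {
    nxt <- character()
    for (u in frontier) {
      tu <- transform[[u]]
      fwd <- registry$edges[registry$edges$from_curie == u, ]
      for (k in seq_len(nrow(fwd))) {
        v <- fwd$to_curie[k]
        if (is.null(transform[[v]])) {
          transform[[v]] <- c(fwd$factor[k] * tu[1], fwd$factor[k] * tu[2] + fwd$offset[k])
          nxt <- c(nxt, v)
        }
      }
      bwd <- registry$edges[registry$edges$to_curie == u, ]
      for (k in seq_len(nrow(bwd))) {
        v <- bwd$from_curie[k]
        if (is.null(transform[[v]])) {
          inv_f <- 1 / bwd$factor[k]
          inv_o <- -bwd$offset[k] / bwd$factor[k]
          transform[[v]] <- c(inv_f * tu[1], inv_f * tu[2] + inv_o)
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
    if (!is.null(transform[[to]]))
      return(setNames(transform[[to]], c("factor", "offset")))
  }
  stop_oceanpack("incompatible_units",
                 sprintf("no conversion between %s and %s: different dimension groups (add an explicit bridge if intended)",
                         from, to))
}

#' Convert a value between registered units
#'
#' @param value Numeric vector.
#' @param from_unit,to_unit UO CURIEs.
#' @param registry A `unit_registry`.
#' @return Converted numeric vector.
#' @export
convert_value <- function(value, from_unit, to_unit, registry) {
  tr <- find_conversion(registry, from_unit, to_unit)
  value * tr[["factor"]] + tr[["offset"]]
}

#' Bridge molar and mass-based seawater concentration units
#'
#' Adds an explicit micromolar to micromole-per-kilogram conversion under an
#' assumed seawater density (kg per litre):
#' `value_umol_per_kg = value_umol_per_L / density`. The assumption is
#' recorded on the registry so downstream provenance can surface it.
#'
#' @param registry A `unit_registry`.
#' @param density Assumed seawater density in kg/L (default 1.025).
#' @return The augmented registry.
#' @export
with_density_bridge <- function(registry, density = 1.025) {
  stopifnot(inherits(registry, "unit_registry"), density > 0)
  registry$edges <- rbind(
    registry$edges,
    data.frame(from_curie = "UO:0000064", to_curie = "UO:0010004",
               factor = 1 / density, offset = 0, stringsAsFactors = FALSE))
  registry$assumptions <- c(
    registry$assumptions,
    sprintf("micromolar<->micromole-per-kilogram bridged assuming seawater density %g kg/L",
            density))
  registry
}

#' @export
print.unit_registry <- function(x, ...) {
  cat(sprintf("<unit registry: %d conversion(s), %d unit(s)>\n",
              nrow(x$edges), length(registry_units(x))))
  for (a in x$assumptions) cat("  assumption:", a, "\n")
  invisible(x)
}
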