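## Semantic harmonization ------------------------------------------------
##
## Cross-package discovery and harmonization: fields are found by their
## attribute-term annotation (optionally expanded through the is-a closure),
## values are converted to one unit per attribute column, and every cell in
## the resulting sample x attribute table keeps full provenance (source
## package, resource, field, original unit, device term). Joins across
## packages are by exact sample-identifier string; no fuzzy matching.

#' Describe an attribute query
#'
#' @param term Target attribute CURIE.
#' @param include_descendants Expand the query through the is-a closure, so a
#'   query for a general term (chlorophyll concentration) also finds fields
#'   annotated with a more precise one (chlorophyll a concentration).
#' @param required_units Optional unit CURIEs the matched field must use.
#' @return An `attribute_query`.
#' @export
attribute_query <- function(term, include_descendants = FALSE,
                            required_units = NULL) {
  structure(list(term = term, include_descendants = include_descendants,
                 required_units = required_units),
            class = "attribute_query")
}

#' Find fields by ontology annotation
#'
#' @param packages List of `package_descriptor`s.
#' @param graph A `term_graph`.
#' @param query An [attribute_query()] (or a bare CURIE, taken as an exact
#'   query).
#' @return Data frame `package`, `resource`, `field`, `curie`, `exact`,
#'   ordered by package, resource, field.
#' @export
search_attributes <- function(packages, graph, query) {
  if (is.character(query)) query <- attribute_query(query)
  assert_in_graph(graph, query$term)
  allowed <- query$term
  if (query$include_descendants)
    allowed <- c(allowed, descendants(graph, query$term))
  rows <- list()
  for (pkg in packages) {
    for (r in pkg$resources) {
      for (f in r$fields) {
        if (is.null(f$rdf_type) || !f$rdf_type$curie %in% allowed) next
        if (!is.null(query$required_units) &&
            (is.null(f$unit_rdf_type) ||
             !f$unit_rdf_type$curie %in% query$required_units)) next
        rows[[length(rows) + 1L]] <- data.frame(
          package = pkg$name, resource = r$name, field = f$name,
          curie = f$rdf_type$curie, exact = f$rdf_type$curie == query$term,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(package = character(), resource = character(),
               field = character(), curie = character(), exact = logical(),
               stringsAsFactors = FALSE)
  out <- out[order(out$package, out$resource, out$field), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## locate the sample-identifier field of a resource
find_sample_field <- function(res, sample_field = NULL) {
  if (!is.null(sample_field)) {
    if (sample_field %in% vapply(res$fields, function(f) f$name, character(1)))
      return(sample_field)
    return(NULL)
  }
  for (f in res$fields)
    if (!is.null(f$rdf_type) && f$rdf_type$curie == "IAO:0020000")
      return(f$name)
  nms <- vapply(res$fields, function(f) f$name, character(1))
  hit <- grep("accession|sample_?name|^sample$", nms, ignore.case = TRUE)
  if (length(hit)) nms[hit[[1L]]] else NULL
}

#' Build a harmonized sample-by-attribute table
#'
#' Gathers, across packages, every field annotated with one of the requested
#' attribute terms (exact match or, through the is-a closure, a descendant),
#' converts values to a single unit per attribute and joins them by sample
#' identifier. When two sources supply one cell the exact-term source wins
#' over a descendant-term source, then the source carrying a device
#' annotation, then package order; the losing value is logged in
#' `$conflicts`, never silently dropped.
#'
#' @param packages List of `package_descriptor`s.
#' @param dirs Character vector of package directories, parallel to
#'   `packages`.
#' @param graph A `term_graph`.
#' @param attributes Character vector of attribute CURIEs to harmonize.
#' @param registry A `unit_registry` for unit conversion.
#' @param sample_field Optional explicit sample-identifier column name; by
#'   default the identifier-annotated or accession/sample-name column.
#' @param target_units Optional named vector `attribute CURIE -> unit CURIE`;
#'   defaults to the unit of the first contributing field per attribute.
#' @return A `harmonized_table`: `values` (data frame, `sample` plus one
#'   numeric column per attribute), `units` (named vector), `provenance` and
#'   `conflicts` data frames, and a `context` slot filled by
#'   [attach_env_context()].
#' @export
build_harmonized_table <- function(packages, dirs, graph, attributes,
                                   registry = load_unit_registry(),
                                   sample_field = NULL, target_units = NULL) {
  stopifnot(length(packages) == length(dirs))
  for (a in attributes) assert_in_graph(graph, a)
  allowed <- lapply(attributes, function(a) c(a, descendants(graph, a)))
  names(allowed) <- attributes
  cand <- list()
  for (p in seq_along(packages)) {
    pkg <- packages[[p]]
    for (r in pkg$resources) {
      sf <- find_sample_field(r, sample_field)
      if (is.null(sf)) next
      relevant <- vapply(r$fields, function(f)
        !is.null(f$rdf_type) &&
          any(vapply(allowed, function(a) f$rdf_type$curie %in% a, logical(1))),
        logical(1))
      if (!any(relevant)) next
      tab <- load_resource(pkg, r$name, dirs[[p]])
      sj <- match(sf, tab$columns)
      ids <- as.character(tab$data[[sj]])
      ids[tab$null_mask[, sj]] <- NA
      dup <- unique(ids[!is.na(ids) & duplicated(ids)])
      if (length(dup))
        stop_oceanpack("duplicate_sample",
                       sprintf("resource \"%s\": duplicate sample id(s): %s",
                               r$name, paste(dup, collapse = ", ")))
      for (j in which(relevant)) {
        f <- r$fields[[j]]
        attr_hits <- attributes[vapply(allowed, function(a)
          f$rdf_type$curie %in% a, logical(1))]
        keep <- !tab$null_mask[, j] & !tab$error_mask[, j] & !is.na(ids)
        if (!any(keep)) next
        for (a in attr_hits) {
          cand[[length(cand) + 1L]] <- data.frame(
            sample = ids[keep], attribute = a,
            value = as.numeric(tab$data[[j]][keep]),
            package = pkg$name, package_order = p, resource = r$name,
            field = f$name,
            original_unit = if (!is.null(f$unit_rdf_type))
              f$unit_rdf_type$curie else NA_character_,
            device = if (!is.null(f$measurement_source_rdf_type))
              f$measurement_source_rdf_type$curie else NA_character_,
            exact = f$rdf_type$curie == a,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(sample = character(), attribute = character(), value = numeric(),
               package = character(), package_order = integer(),
               resource = character(), field = character(),
               original_unit = character(), device = character(),
               exact = logical(), stringsAsFactors = FALSE)

  ## one unit per attribute column
  units <- setNames(rep(NA_character_, length(attributes)), attributes)
  for (a in attributes) {
    units[[a]] <- if (!is.null(target_units) && a %in% names(target_units))
      target_units[[a]]
    else {
      u <- cand$original_unit[cand$attribute == a]
      u <- u[!is.na(u)]
      if (length(u)) u[[1L]] else NA_character_
    }
  }
  if (nrow(cand)) {
    cand$value_converted <- cand$value
    for (k in seq_len(nrow(cand))) {
      from <- cand$original_unit[k]
      to <- units[[cand$attribute[k]]]
      if (!is.na(from) && !is.na(to) && from != to)
        cand$value_converted[k] <- convert_value(cand$value[k], from, to, registry)
    }
  } else cand$value_converted <- numeric()

  ## conflict resolution: exact > has-device > package order
  win <- rep(TRUE, nrow(cand))
  if (nrow(cand)) {
    key <- paste(cand$sample, cand$attribute, sep = "\r")
    rank <- order(!cand$exact, is.na(cand$device), cand$package_order,
                  cand$resource, cand$field)
    first <- !duplicated(key[rank])
    win[rank] <- first
  }
  winners <- cand[win, , drop = FALSE]
  losers <- cand[!win, , drop = FALSE]

  samples <- sort(unique(winners$sample))
  values <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (a in attributes) {
    col <- rep(NA_real_, length(samples))
    sub <- winners[winners$attribute == a, , drop = FALSE]
    col[match(sub$sample, samples)] <- sub$value_converted
    values[[a]] <- col
  }
  prov_cols <- c("sample", "attribute", "package", "resource", "field",
                 "original_unit", "device", "value")
  structure(
    list(values = values, units = units,
         provenance = winners[, prov_cols, drop = FALSE],
         conflicts = losers[, prov_cols, drop = FALSE],
         context = NULL),
    class = "harmonized_table")
}

#' @export
print.harmonized_table <- function(x, ...) {
  cat(sprintf("<harmonized table: %d sample(s) x %d attribute(s); %d conflict(s) logged%s>\n",
              nrow(x$values), length(x$units), nrow(x$conflicts),
              if (!is.null(x$context)) "; env context attached" else ""))
  invisible(x)
}

#' Summarize measurement-device heterogeneity
#'
#' Lists the distinct device terms behind each harmonized attribute column.
#' Mixed devices never block harmonization, but they are surfaced so users
#' can decide what is comparable.
#'
#' @param table A `harmonized_table`.
#' @return Data frame `attribute`, `n_devices`, `devices` (comma-separated).
#' @export
device_summary <- function(table) {
  out <- lapply(names(table$units), function(a) {
    d <- unique(table$provenance$device[table$provenance$attribute == a])
    d <- d[!is.na(d)]
    data.frame(attribute = a, n_devices = length(d),
               devices = paste(sort(d), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## -- environmental context ----------------------------------------------

ENV_CONTEXT_ROOTS <- c(biome = "ENVO:00000428",
                       feature = "ENVO:00002297",
                       material = "ENVO:00010483")

#' Attach ENVO environmental context to a harmonized table
#'
#' Context columns (biome, environmental feature, environmental material)
#' are located by their `rdfType` annotation; their cells hold ENVO PURLs or
#' CURIEs describing each sample. Unknown terms are kept and flagged rather
#' than dropped.
#'
#' @param table A `harmonized_table`.
#' @param packages,dirs As in [build_harmonized_table()].
#' @param graph A `term_graph` (for labels and validity flags).
#' @param sample_field Optional explicit sample-identifier column.
#' @return The table with `$context`: data frame `sample`, then per kind
#'   (`biome`, `feature`, `material`) a CURIE column, a `_label` and a
#'   `_known` flag.
#' @export
attach_env_context <- function(table, packages, dirs, graph,
                               sample_field = NULL) {
  samples <- table$values$sample
  ctx <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (kind in names(ENV_CONTEXT_ROOTS)) {
    ctx[[kind]] <- NA_character_
    ctx[[paste0(kind, "_label")]] <- NA_character_
    ctx[[paste0(kind, "_known")]] <- NA
  }
  for (p in seq_along(packages)) {
    pkg <- packages[[p]]
    for (r in pkg$resources) {
      sf <- find_sample_field(r, sample_field)
      if (is.null(sf)) next
      kinds <- vapply(r$fields, function(f)
        if (!is.null(f$rdf_type) && f$rdf_type$curie %in% ENV_CONTEXT_ROOTS)
          names(ENV_CONTEXT_ROOTS)[match(f$rdf_type$curie, ENV_CONTEXT_ROOTS)]
        else NA_character_, character(1))
      if (all(is.na(kinds))) next
      tab <- load_resource(pkg, r$name, dirs[[p]])
      sj <- match(sf, tab$columns)
      ids <- as.character(tab$data[[sj]])
      for (j in which(!is.na(kinds))) {
        kind <- kinds[[j]]
        vals <- as.character(tab$data[[j]])
        ok <- !tab$null_mask[, j] & !is.na(vals) & ids %in% samples
        for (i in which(ok)) {
          curie <- tryCatch(
            if (startsWith(vals[i], "http")) purl_to_curie(vals[i]) else vals[i],
            oceanpack_error = function(e) vals[i])
          row <- match(ids[i], ctx$sample)
          known <- curie %in% graph$terms$curie
          ctx[[kind]][row] <- curie
          ctx[[paste0(kind, "_label")]][row] <-
            if (known) graph$terms$label[match(curie, graph$terms$curie)] else NA_character_
          ctx[[paste0(kind, "_known")]][row] <- known
        }
      }
    }
  }
  table$context <- ctx
  table
}

## -- climate zones -------------------------------------------------------

CLIMATE_ZONE_TERMS <- c(tropical = "ENVO:01000204",
                        temperate = "ENVO:01000206",
                        polar = "ENVO:01000238")

#' Bin latitudes into climate zones
#'
#' Latitude is partitioned into the three major climatic conditions using
#' the astronomical tropic and polar circles: `|lat| < tropic` is tropical,
#' `tropic <= |lat| < polar` temperate, `|lat| >= polar` polar — boundary
#' latitudes go to the poleward bin. Every latitude in \[-90, 90\] falls in
#' exactly one zone.
#'
#' @param latitude Numeric vector of latitudes in degrees.
#' @param tropic,polar Zone cutoffs in degrees (defaults 23.5 and 66.5).
#' @return Factor with levels `tropical`, `temperate`, `polar`; the
#'   zone-to-ENVO mapping is in the `terms` attribute (see
#'   `climate_zone_terms()`).
#' @examples
#' climate_zone(c(0, 23.5, -70))
#' @export
climate_zone <- function(latitude, tropic = 23.5, polar = 66.5) {
  if (any(is.na(latitude)) || any(abs(latitude) > 90))
    stop_oceanpack("domain", "latitude must be in [-90, 90]")
  a <- abs(latitude)
  zone <- ifelse(a < tropic, "tropical", ifelse(a < polar, "temperate", "polar"))
  structure(factor(zone, levels = names(CLIMATE_ZONE_TERMS)),
            terms = CLIMATE_ZONE_TERMS)
}

#' @rdname climate_zone
#' @export
climate_zone_terms <- function() CLIMATE_ZONE_TERMS

## -- sample filtering ----------------------------------------------------

#' Filter harmonized samples by attribute predicates
#'
#' Retains rows satisfying every predicate; a `min`/`max` comparison fails
#' on a missing value, so range predicates imply non-null. The number of
#' removed rows is reported in the `removed` attribute.
#'
#' @param table A `harmonized_table`.
#' @param predicates List of `list(attribute=, min=, max=, non_null=)`
#'   records; absent elements are unconstrained.
#' @return The filtered `harmonized_table`.
#' @export
filter_samples <- function(table, predicates) {
  keep <- rep(TRUE, nrow(table$values))
  for (p in predicates) {
    a <- p$attribute
    if (is.null(a) || !a %in% names(table$values))
      stop_oceanpack("missing_column",
                     sprintf("unknown attribute column: %s", a %||% "<null>"))
    if (!is.null(p$min) && !is.null(p$max) && p$min > p$max)
      stop_oceanpack("column_predicate",
                     sprintf("predicate on %s: min %g > max %g", a, p$min, p$max))
    v <- table$values[[a]]
    if (isTRUE(p$non_null)) keep <- keep & !is.na(v)
    if (!is.null(p$min)) keep <- keep & !is.na(v) & v >= p$min
    if (!is.null(p$max)) keep <- keep & !is.na(v) & v <= p$max
  }
  removed <- sum(!keep)
  kept_ids <- table$values$sample[keep]
  table$values <- table$values[keep, , drop = FALSE]
  rownames(table$values) <- NULL
  table$provenance <- table$provenance[table$provenance$sample %in% kept_ids, ,
                                       drop = FALSE]
  if (!is.null(table$context))
    table$context <- table$context[table$context$sample %in% kept_ids, ,
                                   drop = FALSE]
  attr(table, "removed") <- removed
  table
}
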