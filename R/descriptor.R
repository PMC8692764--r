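## Descriptor model ------------------------------------------------------
##
## A data package is a directory holding a "datapackage.json" descriptor plus
## TSV resource files. The descriptor follows the Frictionless Data Package
## dialect with ontology annotations on fields under the "pm:" namespace:
##   rdfType                      what the column is about (ENVO/PMO/OBI term)
##   pm:unitRdfType               unit of measure (UO term)
##   pm:measurementSourceRdfType  measurement device (OBI term)
##   pm:searchable                exposure flag for discovery interfaces
## The device key is also accepted in the misspelled variant
## "pm:measurmentSourceRdfType" found in the wild; one canonical spelling is
## always written back.

FIELD_TYPES <- c("string", "number", "integer", "datetime")

DEVICE_KEY          <- "pm:measurementSourceRdfType"
DEVICE_KEY_VARIANTS <- c("pm:measurementSourceRdfType", "pm:measurmentSourceRdfType")
RDFTYPE_KEY_VARIANTS <- c("rdfType", "pm:rdfType")
UNIT_KEY            <- "pm:unitRdfType"
SEARCHABLE_KEY      <- "pm:searchable"

KNOWN_FIELD_KEYS <- c("name", "type", "format", "constraints", "missingValues",
                      RDFTYPE_KEY_VARIANTS, UNIT_KEY, DEVICE_KEY_VARIANTS,
                      SEARCHABLE_KEY)
KNOWN_RESOURCE_KEYS <- c("name", "path", "md5", "delimiter", "schema")
KNOWN_PACKAGE_KEYS  <- c("name", "title", "homepage", "licenses", "sources",
                         "resources")

term_ref_or_null <- function(x) {
  if (is.null(x)) return(NULL)
  term_ref(as.character(x))
}

new_field_spec <- function(name, type = "string", format = NULL,
                           missing_values = character(), constraints = NULL,
                           rdf_type = NULL, unit_rdf_type = NULL,
                           measurement_source_rdf_type = NULL,
                           searchable = NA, extra = list()) {
  if (!type %in% FIELD_TYPES)
    stop_oceanpack("schema",
                   sprintf("field \"%s\": unknown declared type \"%s\"", name, type))
  if (!is.null(constraints)) {
    if (!type %in% c("number", "integer"))
      stop_oceanpack("schema",
                     sprintf("field \"%s\": constraints require a numeric type", name))
    if (!is.null(constraints$minimum) && !is.null(constraints$maximum) &&
        constraints$minimum > constraints$maximum)
      stop_oceanpack("schema",
                     sprintf("field \"%s\": constraint minimum exceeds maximum", name))
  }
  structure(
    list(name = name, type = type, format = format,
         missing_values = as.character(missing_values),
         constraints = constraints,
         rdf_type = rdf_type, unit_rdf_type = unit_rdf_type,
         measurement_source_rdf_type = measurement_source_rdf_type,
         searchable = searchable, extra = extra),
    class = "field_spec"
  )
}

#' Declare a resource field
#'
#' Constructs the schema entry for one TSV column, optionally carrying the
#' annotation triad (attribute term, unit term, device term).
#'
#' @param name Column header string.
#' @param type One of `"string"`, `"number"`, `"integer"`, `"datetime"`.
#' @param format Optional strftime-style pattern for datetime fields.
#' @param missing_values Strings that denote a missing cell (matched exactly).
#' @param minimum,maximum Optional inclusive numeric range constraints.
#' @param rdf_type,unit,device CURIE or PURL of the attribute, unit and
#'   measurement-device terms; each may be `NULL`.
#' @param searchable Logical exposure flag; `NA` leaves it unset.
#' @return A `field_spec` object.
#' @export
field_spec <- function(name, type = "string", format = NULL,
                       missing_values = character(),
                       minimum = NULL, maximum = NULL,
                       rdf_type = NULL, unit = NULL, device = NULL,
                       searchable = NA) {
  constraints <- NULL
  if (!is.null(minimum) || !is.null(maximum))
    constraints <- list(minimum = minimum, maximum = maximum)
  new_field_spec(name, type, format, missing_values, constraints,
                 rdf_type = term_ref_or_null(rdf_type),
                 unit_rdf_type = term_ref_or_null(unit),
                 measurement_source_rdf_type = term_ref_or_null(device),
                 searchable = searchable)
}

#' Declare a tabular resource
#'
#' @param name Resource name, unique within the package.
#' @param path Relative path of the TSV file.
#' @param fields List of [field_spec()] objects, in column order.
#' @param md5 32-hex-digit checksum of the file, or `NA` if not yet computed.
#' @param delimiter Field separator (tab by default).
#' @return A `resource_spec` object.
#' @export
resource_spec <- function(name, path, fields = list(), md5 = NA_character_,
                          delimiter = "\t") {
  if (grepl("^([A-Za-z]:)?[/\\\\]", path) || grepl("(^|/)\\.\\.(/|$)", path))
    stop_oceanpack("schema",
                   sprintf("resource \"%s\": path must be relative and may not escape the package (%s)",
                           name, path))
  nms <- vapply(fields, function(f) f$name, character(1))
  if (anyDuplicated(nms))
    stop_oceanpack("schema",
                   sprintf("resource \"%s\": duplicate field names: %s", name,
                           paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  if (!is.na(md5) && !grepl("^[0-9a-f]{32}$", md5))
    stop_oceanpack("schema",
                   sprintf("resource \"%s\": md5 must be 32 hex digits", name))
  structure(
    list(name = name, path = path, md5 = md5, delimiter = delimiter,
         fields = fields, extra = list()),
    class = "resource_spec"
  )
}

#' Assemble a package descriptor
#'
#' @param name Package name.
#' @param resources List of [resource_spec()] objects (at least one).
#' @param title Optional human title.
#' @param licenses,sources Lists of `list(name/title, path)` records.
#' @param homepage Optional URL string.
#' @return A `package_descriptor` object.
#' @export
package_descriptor <- function(name, resources, title = NULL,
                               licenses = list(), sources = list(),
                               homepage = NULL) {
  if (length(resources) < 1L)
    stop_oceanpack("schema", "a package needs at least one resource")
  nms <- vapply(resources, function(r) r$name, character(1))
  if (anyDuplicated(nms))
    stop_oceanpack("schema",
                   sprintf("duplicate resource names: %s",
                           paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  structure(
    list(name = name, title = title, homepage = homepage,
         licenses = licenses, sources = sources,
         resources = resources, extra = list()),
    class = "package_descriptor"
  )
}

## -- parsing -------------------------------------------------------------

first_present <- function(x, keys) {
  for (k in keys) if (!is.null(x[[k]])) return(x[[k]])
  NULL
}

parse_field <- function(f, schema_missing) {
  if (is.null(f$name))
    stop_oceanpack("schema", "field without required key \"name\"")
  mv <- f$missingValues %||% schema_missing
  constraints <- NULL
  if (!is.null(f$constraints)) {
    constraints <- list(
      minimum = if (!is.null(f$constraints$minimum)) as.numeric(f$constraints$minimum),
      maximum = if (!is.null(f$constraints$maximum)) as.numeric(f$constraints$maximum)
    )
  }
  searchable <- f[[SEARCHABLE_KEY]]
  searchable <- if (is.null(searchable)) NA else isTRUE(as.logical(searchable))
  extra <- f[setdiff(names(f), KNOWN_FIELD_KEYS)]
  new_field_spec(
    name = as.character(f$name),
    type = as.character(f$type %||% "string"),
    format = if (!is.null(f$format)) as.character(f$format),
    missing_values = as.character(unlist(mv, use.names = FALSE)),
    constraints = constraints,
    rdf_type = term_ref_or_null(first_present(f, RDFTYPE_KEY_VARIANTS)),
    unit_rdf_type = term_ref_or_null(f[[UNIT_KEY]]),
    measurement_source_rdf_type =
      term_ref_or_null(first_present(f, DEVICE_KEY_VARIANTS)),
    searchable = searchable,
    extra = extra
  )
}

parse_resource <- function(r) {
  for (k in c("name", "path"))
    if (is.null(r[[k]]))
      stop_oceanpack("schema", sprintf("resource without required key \"%s\"", k))
  schema <- r$schema %||% list()
  schema_missing <- as.character(unlist(schema$missingValues %||% list(),
                                        use.names = FALSE))
  fields <- lapply(schema$fields %||% list(), parse_field, schema_missing)
  res <- resource_spec(
    name = as.character(r$name), path = as.character(r$path),
    fields = fields,
    md5 = if (!is.null(r$md5)) as.character(r$md5) else NA_character_,
    delimiter = as.character(r$delimiter %||% "\t")
  )
  res$extra <- r[setdiff(names(r), KNOWN_RESOURCE_KEYS)]
  res
}

#' Read a package descriptor from JSON text
#'
#' Parses a `datapackage.json` descriptor (Frictionless dialect plus `pm:`
#' annotation extensions) into a `package_descriptor`. Unknown keys at the
#' package, resource and field level are preserved verbatim so that
#' [save_descriptor()] round-trips them. A UTF-8 byte-order mark is stripped.
#'
#' @param json_text Descriptor JSON as a single string, or a file path to read.
#' @return A `package_descriptor` object.
#' @seealso [save_descriptor()], [load_package_dir()]
#' @export
load_descriptor <- function(json_text) {
  if (length(json_text) == 1L && !grepl("[{]", json_text) && file.exists(json_text))
    json_text <- readChar(json_text, file.size(json_text), useBytes = TRUE)
  json_text <- sub("^﻿", "", enc2utf8(json_text))
  doc <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e)
      stop_oceanpack("json_parse", paste("malformed descriptor JSON:",
                                         conditionMessage(e)))
  )
  if (is.null(doc$name))
    stop_oceanpack("schema", "descriptor without required key \"name\"")
  if (is.null(doc$resources) || length(doc$resources) == 0L)
    stop_oceanpack("schema", "descriptor without required key \"resources\"")
  pkg <- package_descriptor(
    name = as.character(doc$name),
    resources = lapply(doc$resources, parse_resource),
    title = if (!is.null(doc$title)) as.character(doc$title),
    licenses = doc$licenses %||% list(),
    sources = doc$sources %||% list(),
    homepage = if (!is.null(doc$homepage)) as.character(doc$homepage)
  )
  pkg$extra <- doc[setdiff(names(doc), KNOWN_PACKAGE_KEYS)]
  pkg
}

## -- serialization -------------------------------------------------------

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

sorted_extra <- function(x) if (length(x)) x[order(names(x))] else NULL

field_to_list <- function(f) {
  out <- drop_null(list(
    name = f$name,
    type = f$type,
    format = f$format,
    constraints = if (!is.null(f$constraints)) drop_null(f$constraints),
    missingValues = if (length(f$missing_values)) as.list(f$missing_values)
  ))
  if (!is.null(f$rdf_type)) out[["rdfType"]] <- f$rdf_type$purl
  if (!is.null(f$unit_rdf_type)) out[[UNIT_KEY]] <- f$unit_rdf_type$purl
  if (!is.null(f$measurement_source_rdf_type))
    out[[DEVICE_KEY]] <- f$measurement_source_rdf_type$purl
  if (!is.na(f$searchable)) out[[SEARCHABLE_KEY]] <- f$searchable
  c(out, sorted_extra(f$extra))
}

resource_to_list <- function(r) {
  out <- drop_null(list(
    name = r$name,
    path = r$path,
    md5 = if (!is.na(r$md5)) r$md5,
    delimiter = if (!identical(r$delimiter, "\t")) r$delimiter,
    schema = list(fields = lapply(r$fields, field_to_list))
  ))
  c(out, sorted_extra(r$extra))
}

#' Serialize a package descriptor to canonical JSON
#'
#' Emits JSON with a fixed key order and indentation so that structurally
#' equal descriptors serialize to byte-identical text. The device annotation
#' is always written under the canonical `pm:measurementSourceRdfType`
#' spelling, and term annotations are written as PURLs.
#'
#' @param pkg A `package_descriptor`.
#' @param path Optional file to write to (UTF-8, trailing newline).
#' @return The JSON text, invisibly when `path` is given.
#' @export
save_descriptor <- function(pkg, path = NULL) {
  stopifnot(inherits(pkg, "package_descriptor"))
  out <- drop_null(list(
    name = pkg$name,
    title = pkg$title,
    homepage = pkg$homepage,
    licenses = if (length(pkg$licenses)) pkg$licenses,
    sources = if (length(pkg$sources)) pkg$sources
  ))
  out <- c(out, sorted_extra(pkg$extra))
  out$resources <- lapply(pkg$resources, resource_to_list)
  txt <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = 2, digits = NA,
                          null = "null")
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' @export
print.package_descriptor <- function(x, ...) {
  cat(sprintf("<data package \"%s\": %d resource(s)>\n", x$name,
              length(x$resources)))
  for (r in x$resources)
    cat(sprintf("  %s (%s): %d field(s)\n", r$name, r$path, length(r$fields)))
  invisible(x)
}

## -- annotation enumeration ---------------------------------------------

#' Enumerate annotation triads
#'
#' Lists, for every field of every resource, the three ontology annotations
#' that make a column machine-reusable: the attribute term (`rdfType`), the
#' unit term and the measurement-device term. Absent members are `NA`, which
#' is what the completeness audit keys on.
#'
#' @param pkg A `package_descriptor`.
#' @return A data frame with columns `resource`, `field`, `type`, `rdf_type`,
#'   `unit`, `device` (CURIEs or `NA`) and logical `complete`.
#' @export
list_annotation_triads <- function(pkg) {
  rows <- list()
  for (r in pkg$resources) {
    for (f in r$fields) {
      rows[[length(rows) + 1L]] <- data.frame(
        resource = r$name, field = f$name, type = f$type,
        rdf_type = if (!is.null(f$rdf_type)) f$rdf_type$curie else NA_character_,
        unit = if (!is.null(f$unit_rdf_type)) f$unit_rdf_type$curie else NA_character_,
        device = if (!is.null(f$measurement_source_rdf_type))
          f$measurement_source_rdf_type$curie else NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(resource = character(), field = character(), type = character(),
               rdf_type = character(), unit = character(), device = character(),
               stringsAsFactors = FALSE)
  out$complete <- !is.na(out$rdf_type) &
    (!out$type %in% c("number", "integer") | (!is.na(out$unit) & !is.na(out$device)))
  out
}

#' Extract sequence-accession links from a loaded resource
#'
#' Data packages link out to INSDC sequence records through a column of
#' accession strings. The accession column is designated either explicitly,
#' by an identifier `rdfType` annotation, or by a column-name pattern.
#'
#' @param pkg A `package_descriptor`.
#' @param table A `parsed_table` from [load_resource()].
#' @param field Optional explicit column name.
#' @param pattern Regex fallback used to locate the column by name.
#' @param dedupe Drop duplicate accessions, keeping first occurrence.
#' @return Character vector of non-missing accessions in row order; empty
#'   (with a warning of class `oceanpack_no_accession_column`) when no
#'   accession column can be designated.
#' @export
list_sequence_links <- function(pkg, table, field = NULL,
                                pattern = "accession|sample_?name",
                                dedupe = FALSE) {
  res <- NULL
  for (r in pkg$resources) if (r$name == table$resource) res <- r
  if (is.null(res))
    stop_oceanpack("missing_resource",
                   sprintf("resource \"%s\" not in package", table$resource))
  if (is.null(field)) {
    for (f in res$fields) {
      if (!is.null(f$rdf_type) && f$rdf_type$curie == "IAO:0020000") {
        field <- f$name
        break
      }
    }
  }
  if (is.null(field)) {
    hits <- grep(pattern, table$columns, ignore.case = TRUE, value = TRUE)
    field <- if (length(hits)) hits[[1L]] else NULL
  }
  if (is.null(field)) {
    warn_oceanpack("no_accession_column",
                   sprintf("resource \"%s\": no accession column designated",
                           table$resource))
    return(character())
  }
  j <- match(field, table$columns)
  if (is.na(j))
    stop_oceanpack("missing_column",
                   sprintf("column \"%s\" not in resource \"%s\"", field,
                           table$resource))
  vals <- as.character(table$data[[j]])
  vals <- vals[!table$null_mask[, j]]
  if (dedupe) vals <- vals[!duplicated(vals)]
  vals
}
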