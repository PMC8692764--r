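## Validation ------------------------------------------------------------
##
## Three check families over a data package, each producing located, coded
## issues:
##   transferability  - resource files present, MD5 checksums match
##   cell conformance - declared type, datetime format, numeric range
##   annotation audit - triad completeness and term resolvability
## Severity policy: everything is an error except an incomplete annotation
## triad, which is a warning — published packages legitimately ship with
## absent device terms when the source repository never recorded the device.

ISSUE_CODES <- c("MISSING_FILE", "CHECKSUM_MISMATCH", "TYPE_ERROR",
                 "FORMAT_ERROR", "CONSTRAINT_VIOLATION", "HEADER_MISMATCH",
                 "MISSING_ANNOTATION", "UNKNOWN_TERM")

issue <- function(code, resource, row = NA_integer_, column = NA_character_,
                  detail = "") {
  stopifnot(code %in% ISSUE_CODES)
  data.frame(
    code = code,
    severity = if (code == "MISSING_ANNOTATION") "warning" else "error",
    resource = resource, row = as.integer(row), column = column,
    detail = detail, stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(code = character(), severity = character(), resource = character(),
             row = integer(), column = character(), detail = character(),
             stringsAsFactors = FALSE)
}

bind_issues <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(no_issues())
  do.call(rbind, lst)
}

order_issues <- function(issues) {
  if (!nrow(issues)) return(issues)
  o <- order(issues$resource,
             ifelse(is.na(issues$row), -1L, issues$row),
             ifelse(is.na(issues$column), "", issues$column),
             issues$code)
  out <- issues[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_validation_report <- function(package_name, issues) {
  issues <- order_issues(issues)
  counts <- table(factor(issues$code, levels = ISSUE_CODES))
  structure(
    list(package_name = package_name, issues = issues,
         counts = setNames(as.integer(counts), names(counts)),
         pass = !any(issues$severity == "error")),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation of \"%s\": %s; %d issue(s)>\n", x$package_name,
              if (x$pass) "PASS" else "FAIL", nrow(x$issues)))
  nz <- x$counts[x$counts > 0]
  for (code in names(nz)) cat(sprintf("  %-20s %d\n", code, nz[[code]]))
  invisible(x)
}

## -- transferability -----------------------------------------------------

#' Check complete transferability of a package
#'
#' A package is completely transferable when every declared resource file
#' exists under the package directory and its MD5 checksum matches the one
#' recorded in the descriptor — any corruption or omission in transit is
#' caught before the data are reused.
#'
#' @param pkg A `package_descriptor`.
#' @param base_dir Package directory.
#' @return A `validation_report` with `MISSING_FILE` / `CHECKSUM_MISMATCH`
#'   issues.
#' @export
verify_transferability <- function(pkg, base_dir) {
  iss <- list()
  for (r in pkg$resources) {
    path <- file.path(base_dir, r$path)
    if (!file.exists(path)) {
      iss[[length(iss) + 1L]] <-
        issue("MISSING_FILE", r$name, detail = sprintf("file not found: %s", r$path))
      next
    }
    if (!is.na(r$md5)) {
      got <- unname(tools::md5sum(path))
      if (is.na(got)) {
        iss[[length(iss) + 1L]] <-
          issue("MISSING_FILE", r$name, detail = sprintf("file unreadable: %s", r$path))
      } else if (!identical(got, r$md5)) {
        iss[[length(iss) + 1L]] <-
          issue("CHECKSUM_MISMATCH", r$name,
                detail = sprintf("declared %s, computed %s", r$md5, got))
      }
    }
  }
  new_validation_report(pkg$name, bind_issues(iss))
}

## -- cell conformance ----------------------------------------------------

check_datetime_format <- function(x, fmt) {
  parsed <- strptime(x, fmt, tz = "UTC")
  !is.na(parsed) & format(parsed, fmt, tz = "UTC") == x
}

#' Validate table cells against field specs
#'
#' Emits `TYPE_ERROR` for cells that failed typed parsing, `FORMAT_ERROR`
#' for datetime cells not matching the declared strftime-style pattern, and
#' `CONSTRAINT_VIOLATION` for numeric cells outside the inclusive
#' \[minimum, maximum\] range. Null cells generate no issues.
#'
#' @param table A `parsed_table`.
#' @param specs List of `field_spec`s matching the table's columns.
#' @return Issue data frame (see [validate_package()]).
#' @export
validate_cells <- function(table, specs) {
  nms <- vapply(specs, function(f) f$name, character(1))
  if (!identical(nms, table$columns))
    return(issue("HEADER_MISMATCH", table$resource,
                 detail = sprintf("specs [%s] vs columns [%s]",
                                  paste(nms, collapse = ", "),
                                  paste(table$columns, collapse = ", "))))
  iss <- list()
  for (j in seq_along(specs)) {
    f <- specs[[j]]
    nulls <- table$null_mask[, j]
    errs <- which(table$error_mask[, j])
    for (i in errs)
      iss[[length(iss) + 1L]] <-
        issue("TYPE_ERROR", table$resource, i, f$name,
              sprintf("\"%s\" is not a valid %s", table$raw[i, j], f$type))
    if (f$type == "datetime" && !is.null(f$format)) {
      vals <- table$raw[, j]
      check <- which(!nulls)
      if (length(check)) {
        ok <- check_datetime_format(vals[check], f$format)
        for (i in check[!ok])
          iss[[length(iss) + 1L]] <-
            issue("FORMAT_ERROR", table$resource, i, f$name,
                  sprintf("\"%s\" does not match format \"%s\"", vals[i], f$format))
      }
    }
    if (!is.null(f$constraints) && f$type %in% c("number", "integer")) {
      v <- table$data[[j]]
      lo <- f$constraints$minimum
      hi <- f$constraints$maximum
      bad <- !is.na(v) &
        ((if (!is.null(lo)) v < lo else FALSE) |
         (if (!is.null(hi)) v > hi else FALSE))
      for (i in which(bad))
        iss[[length(iss) + 1L]] <-
          issue("CONSTRAINT_VIOLATION", table$resource, i, f$name,
                sprintf("%g outside [%s, %s]", v[i],
                        if (is.null(lo)) "-Inf" else format(lo),
                        if (is.null(hi)) "Inf" else format(hi)))
    }
  }
  bind_issues(iss)
}

## -- annotation audit ----------------------------------------------------

#' Audit annotation completeness and term validity
#'
#' Every field should carry an attribute term (`rdfType`); numeric fields
#' should additionally carry a unit term and a measurement-device term.
#' Absent members yield `MISSING_ANNOTATION` warnings. Any annotation whose
#' CURIE does not resolve in the term graph yields an `UNKNOWN_TERM` error.
#'
#' @param pkg A `package_descriptor`.
#' @param graph A `term_graph`.
#' @return Issue data frame.
#' @export
audit_annotations <- function(pkg, graph) {
  iss <- list()
  known <- graph$terms$curie
  for (r in pkg$resources) {
    for (f in r$fields) {
      numeric <- f$type %in% c("number", "integer")
      members <- list(rdfType = f$rdf_type)
      if (numeric)
        members <- c(members, list(`pm:unitRdfType` = f$unit_rdf_type,
                                   `pm:measurementSourceRdfType` = f$measurement_source_rdf_type))
      for (key in names(members)) {
        m <- members[[key]]
        if (is.null(m)) {
          iss[[length(iss) + 1L]] <-
            issue("MISSING_ANNOTATION", r$name, column = f$name,
                  detail = sprintf("no %s annotation", key))
        } else if (!m$curie %in% known) {
          iss[[length(iss) + 1L]] <-
            issue("UNKNOWN_TERM", r$name, column = f$name,
                  detail = sprintf("%s term %s not in graph", key, m$curie))
        }
      }
    }
  }
  bind_issues(iss)
}

## -- combined ------------------------------------------------------------

#' Validate a data package
#'
#' Runs all check families — transferability, per-cell conformance for every
#' loadable resource, and (when a term graph is supplied) the annotation
#' audit — and returns one report with deterministically ordered issues
#' (resource, row, column, code). Problems are reported, never raised.
#'
#' @param pkg A `package_descriptor`.
#' @param base_dir Package directory.
#' @param graph Optional `term_graph` enabling the annotation audit.
#' @return A `validation_report`: `issues` data frame (`code`, `severity`,
#'   `resource`, `row`, `column`, `detail`), per-code `counts`, and `pass`
#'   (true iff no error-severity issue).
#' @examples
#' \dontrun{
#' pkg <- load_descriptor(file.path(dir, "datapackage.json"))
#' validate_package(pkg, dir, load_term_table(oceanpack_term_table()))
#' }
#' @export
validate_package <- function(pkg, base_dir, graph = NULL) {
  transfer <- verify_transferability(pkg, base_dir)
  iss <- list(transfer$issues)
  missing <- transfer$issues$resource[transfer$issues$code == "MISSING_FILE"]
  for (r in pkg$resources) {
    if (r$name %in% missing) next
    tab <- tryCatch(load_resource(pkg, r$name, base_dir),
                    oceanpack_header = function(e) e)
    if (inherits(tab, "condition")) {
      iss[[length(iss) + 1L]] <-
        issue("HEADER_MISMATCH", r$name, detail = conditionMessage(tab))
      next
    }
    iss[[length(iss) + 1L]] <- validate_cells(tab, r$fields)
  }
  if (!is.null(graph)) iss[[length(iss) + 1L]] <- audit_annotations(pkg, graph)
  new_validation_report(pkg$name, bind_issues(iss))
}
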