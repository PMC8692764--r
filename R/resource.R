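## Resource loading ------------------------------------------------------
##
## TSV cells are parsed against the declared field type. A raw string listed
## in the field's missing-value checklist becomes a null cell (exact string
## match — "NA " is not "NA"). A non-null cell that fails to parse is carried
## as a typed-error cell, keeping its raw text and coordinates, so the
## validator can report it; loading never silently coerces and never fails on
## bad cell content.

parse_typed_column <- function(raw, type) {
  switch(type,
    number = suppressWarnings(as.numeric(raw)),
    integer = {
      ok <- grepl("^[+-]?[0-9]+$", raw)
      out <- rep(NA_integer_, length(raw))
      out[ok] <- as.integer(raw[ok])
      out
    },
    ## datetime cells stay textual; format conformance is a validator concern
    string = ,
    datetime = raw
  )
}

#' Load a declared TSV resource into a typed table
#'
#' Reads the resource file, checks the header against the declared fields,
#' applies per-field missing-value substitution and parses each cell to its
#' declared type. Parse failures become typed-error cells (flagged in
#' `error_mask`, value `NA`) rather than errors, so that [validate_cells()]
#' can locate them.
#'
#' @param pkg A `package_descriptor`.
#' @param resource_name Name of the resource to load.
#' @param base_dir Directory the resource paths are relative to.
#' @return A `parsed_table`: list with `resource`, `columns`, `data` (typed
#'   data frame, `NA` for null or errored cells), `null_mask` and
#'   `error_mask` (logical row x column matrices), `raw` (character matrix of
#'   original cell text) and `line_numbers` (file line of each data row).
#' @export
load_resource <- function(pkg, resource_name, base_dir) {
  res <- NULL
  for (r in pkg$resources) if (r$name == resource_name) res <- r
  if (is.null(res))
    stop_oceanpack("missing_resource",
                   sprintf("resource \"%s\" not in package \"%s\"",
                           resource_name, pkg$name))
  path <- file.path(base_dir, res$path)
  if (!file.exists(path))
    stop_oceanpack("missing_resource",
                   sprintf("resource file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines)) lines[1] <- sub("^﻿", "", lines[1])
  if (!length(lines))
    stop_oceanpack("header",
                   sprintf("resource \"%s\": file is empty, no header row",
                           resource_name))
  declared <- vapply(res$fields, function(f) f$name, character(1))
  header <- strsplit(lines[[1L]], res$delimiter, fixed = TRUE)[[1L]]
  if (!identical(header, declared))
    stop_oceanpack("header",
                   sprintf("resource \"%s\": header mismatch; missing: [%s], unexpected: [%s]",
                           resource_name,
                           paste(setdiff(declared, header), collapse = ", "),
                           paste(setdiff(header, declared), collapse = ", ")))
  body <- lines[-1L]
  n <- length(body)
  p <- length(declared)
  raw <- matrix("", nrow = n, ncol = p, dimnames = list(NULL, declared))
  if (n > 0L) {
    cells <- strsplit(body, res$delimiter, fixed = TRUE)
    for (i in seq_len(n)) {
      row <- cells[[i]]
      ## trailing empty cells are dropped by strsplit; pad back
      length(row) <- p
      row[is.na(row)] <- ""
      if (length(row) != p)
        stop_oceanpack("header",
                       sprintf("resource \"%s\": row %d has %d cells, expected %d",
                               resource_name, i, length(cells[[i]]), p))
      raw[i, ] <- row
    }
  }
  null_mask <- matrix(FALSE, n, p, dimnames = list(NULL, declared))
  error_mask <- matrix(FALSE, n, p, dimnames = list(NULL, declared))
  data <- vector("list", p)
  names(data) <- declared
  for (j in seq_len(p)) {
    f <- res$fields[[j]]
    col_raw <- raw[, j]
    nulls <- col_raw %in% f$missing_values
    parsed <- parse_typed_column(col_raw, f$type)
    errs <- !nulls & is.na(parsed) & f$type %in% c("number", "integer")
    parsed[nulls] <- NA
    null_mask[, j] <- nulls
    error_mask[, j] <- errs
    if (f$type %in% c("string", "datetime")) parsed[nulls] <- NA_character_
    data[[j]] <- parsed
  }
  structure(
    list(resource = resource_name, columns = declared,
         data = as.data.frame(data, optional = TRUE, stringsAsFactors = FALSE,
                              check.names = FALSE),
         null_mask = null_mask, error_mask = error_mask, raw = raw,
         line_numbers = if (n) seq_len(n) + 1L else integer()),
    class = "parsed_table"
  )
}

#' @export
print.parsed_table <- function(x, ...) {
  cat(sprintf("<parsed table \"%s\": %d row(s) x %d field(s); %d null, %d typed-error cell(s)>\n",
              x$resource, nrow(x$raw), length(x$columns),
              sum(x$null_mask), sum(x$error_mask)))
  invisible(x)
}

#' @export
dim.parsed_table <- function(x) dim(x$raw)

#' Load a package directory
#'
#' Convenience wrapper: reads `datapackage.json` from `dir` and returns the
#' descriptor together with the directory, the unit used by most downstream
#' operations.
#'
#' @param dir Package directory containing `datapackage.json`.
#' @return A list with elements `descriptor` and `dir`.
#' @export
load_package_dir <- function(dir) {
  path <- file.path(dir, "datapackage.json")
  if (!file.exists(path))
    stop_oceanpack("missing_resource",
                   sprintf("no datapackage.json under %s", dir))
  list(descriptor = load_descriptor(path), dir = dir)
}
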