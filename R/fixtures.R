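## Synthetic fixtures ----------------------------------------------------
##
## Deterministic generators standing in for deposited data packages so every
## stage is testable offline. Each generator returns (or writes) data plus a
## manifest recording its own ground truth — the injected validation issues,
## the true nutrient slope, which samples got both nutrients, per-taxon
## depth-effect signs — which downstream tests use as the oracle. Identical
## (params, seed) always yield identical bytes.

fmt_num <- function(x, digits) {
  out <- formatC(round(x, digits), format = "f", digits = digits)
  sub("^-(0\\.?0*)$", "\\1", out) # avoid "-0.0000"
}

#' Generate Redfield-structured nutrient data
#'
#' Emulates open-ocean nutrient stoichiometry: nitrate is drawn from a
#' gamma-shaped positive distribution (shape 2, mean 16 uM, resampled above
#' 40 uM to stay in the observed regime) and phosphate follows
#' `true_slope * nitrate` plus Gaussian noise, floored at zero. Optional
#' outliers emulate anthropogenically influenced freshwater-lake samples
#' that break the marine ratio: high nitrate (37-40 uM) with near-zero
#' phosphate, tagged with the freshwater-lake biome/feature context.
#'
#' @param n Number of marine samples (>= 10).
#' @param true_slope True phosphate/nitrate slope (default 1/16).
#' @param noise_sd SD of the phosphate noise, in uM (>= 0).
#' @param n_outliers Number of freshwater outlier samples appended.
#' @param seed Integer seed.
#' @return List with `data` (data frame: `sample`, `nitrate`, `phosphate`,
#'   `biome`, `feature`) and `manifest` (generator parameters, outlier row
#'   indices).
#' @export
generate_redfield_data <- function(n, true_slope = 1 / 16, noise_sd = 0.2,
                                   n_outliers = 0, seed = 1) {
  if (n < 10) stop_oceanpack("parameter", "need n >= 10")
  if (noise_sd < 0) stop_oceanpack("parameter", "noise_sd must be >= 0")
  with_seed(seed, {
    nitrate <- rgamma(n, shape = 2, rate = 0.125)
    while (any(nitrate > 40))
      nitrate[nitrate > 40] <- rgamma(sum(nitrate > 40), shape = 2, rate = 0.125)
    phosphate <- pmax(true_slope * nitrate + rnorm(n, 0, noise_sd), 0)
    biome <- rep("ENVO:00000447", n)
    feature <- rep("ENVO:01001581", n)
    if (n_outliers > 0) {
      nitrate <- c(nitrate, runif(n_outliers, 37, 40))
      phosphate <- c(phosphate, pmax(rnorm(n_outliers, 0, 0.02), 0))
      biome <- c(biome, rep("ENVO:01000252", n_outliers))
      feature <- c(feature, rep("ENVO:00000021", n_outliers))
    }
    total <- n + n_outliers
    list(
      data = data.frame(
        sample = sprintf("S%04d", seq_len(total)),
        nitrate = nitrate, phosphate = phosphate,
        biome = biome, feature = feature, stringsAsFactors = FALSE),
      manifest = list(seed = seed, n = n, true_slope = true_slope,
                      noise_sd = noise_sd,
                      outlier_rows = if (n_outliers) n + seq_len(n_outliers)
                                     else integer()))
  })
}

## default field schema of a generated package ---------------------------

default_package_fields <- function() {
  list(
    samples = list(
      field_spec("sample_name", "string", rdf_type = "IAO:0020000",
                 searchable = TRUE),
      field_spec("collection_date", "datetime", format = "%Y-%m-%dT%H:%M:%SZ",
                 rdf_type = "OBI:0001619"),
      field_spec("latitude", "number", minimum = -90, maximum = 90,
                 rdf_type = "OBI:0001620", unit = "UO:0000185",
                 device = "OBI:0000968"),
      field_spec("longitude", "number", minimum = -180, maximum = 180,
                 rdf_type = "OBI:0001621", unit = "UO:0000185",
                 device = "OBI:0000968"),
      field_spec("depth", "number", minimum = 0, maximum = 11000,
                 rdf_type = "PATO:0001595", unit = "UO:0000008",
                 device = "OBI:0000968"),
      field_spec("temperature", "number", minimum = -5, maximum = 45,
                 rdf_type = "ENVO:09200014", unit = "UO:0000027",
                 device = "OBI:0000968"),
      field_spec("biome", "string", rdf_type = "ENVO:00000428"),
      field_spec("env_feature", "string", rdf_type = "ENVO:00002297"),
      field_spec("env_material", "string", rdf_type = "ENVO:00010483")
    ),
    nutrients = list(
      field_spec("sample_name", "string", rdf_type = "IAO:0020000",
                 searchable = TRUE),
      field_spec("nitrate", "number", minimum = 0, maximum = 100,
                 missing_values = "NA", rdf_type = "ENVO:3100022",
                 unit = "UO:0000064", device = "OBI:0400115"),
      field_spec("phosphate", "number", minimum = 0, maximum = 10,
                 missing_values = "NA", rdf_type = "TEMP:0000001",
                 unit = "UO:0000064", device = "OBI:0400115")
    )
  )
}

INJECTION_KINDS <- c("corrupt_file", "delete_file", "type_error",
                     "out_of_range", "bad_format", "strip_annotation",
                     "unknown_term")

write_tsv_text <- function(df, path) {
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
}

## flip the first digit found in the file: a single-byte corruption that
## leaves the table parseable, so only the checksum check fires
flip_one_byte <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(raw)
  pos <- regexpr("[0-9]", txt)
  if (pos < 0) stop_oceanpack("parameter", "no digit to corrupt in file")
  d <- as.integer(substr(txt, pos, pos))
  substr(txt, pos, pos) <- as.character((d + 1L) %% 10L)
  writeBin(charToRaw(txt), path)
}

#' Generate a synthetic data package with optional error injections
#'
#' Writes a complete package directory — `datapackage.json` plus two TSV
#' resources (`samples`: coordinates, datetime, temperature, depth and ENVO
#' context columns; `nutrients`: nitrate and phosphate with Redfield
#' structure) — with correct MD5 checksums and fully annotated triads, so a
#' clean package validates with zero issues. Each injection then plants one
#' known defect and records the exact issue the validator must report:
#'
#' * `corrupt_file` — flips one byte after checksumming (`CHECKSUM_MISMATCH`)
#' * `delete_file` — removes the file (`MISSING_FILE`)
#' * `type_error` — non-numeric text in a numeric cell (`TYPE_ERROR`)
#' * `out_of_range` — latitude 150, the swapped-lat/lon signature
#'   (`CONSTRAINT_VIOLATION`)
#' * `bad_format` — datetime not matching the declared pattern
#'   (`FORMAT_ERROR`)
#' * `strip_annotation` — drops a triad member (`MISSING_ANNOTATION`)
#' * `unknown_term` — annotation CURIE absent from the graph (`UNKNOWN_TERM`)
#'
#' @param dir Output directory (created; must not already contain a package).
#' @param n_samples Number of samples (>= 1).
#' @param injections List of `list(kind=, resource=, row=, field=, ...)`
#'   records; see [sample_injections()] for a random generator.
#' @param null_rate Fraction of nutrient cells set to the declared missing
#'   value `"NA"`.
#' @param seed Integer seed.
#' @return Invisibly, the `FixtureManifest`: generator parameters, the
#'   descriptor, written data frames, per-sample nutrient availability, and
#'   `expected_issues` — the data frame [validate_package()] must reproduce
#'   exactly.
#' @export
generate_package <- function(dir, n_samples = 10, injections = list(),
                             null_rate = 0, seed = 1) {
  if (n_samples < 1) stop_oceanpack("parameter", "need n_samples >= 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fields <- default_package_fields()
  nut <- generate_redfield_data(max(n_samples, 10), seed = seed)$data[seq_len(n_samples), ]
  features <- c("ENVO:01000326", "ENVO:00000213", "ENVO:01001581")
  tabs <- with_seed(seed + 1L, {
    samples <- data.frame(
      sample_name = sprintf("S%04d", seq_len(n_samples)),
      collection_date = sprintf("2015-06-%02dT10:30:00Z",
                                (seq_len(n_samples) - 1L) %% 28L + 1L),
      latitude = fmt_num(runif(n_samples, -85, 85), 4),
      longitude = fmt_num(runif(n_samples, -179, 179), 4),
      depth = fmt_num(runif(n_samples, 5, 200), 1),
      temperature = fmt_num(runif(n_samples, 2, 30), 2),
      biome = "ENVO:00000447",
      env_feature = features[(seq_len(n_samples) - 1L) %% 3L + 1L],
      env_material = "ENVO:00002010",
      stringsAsFactors = FALSE)
    nutrients <- data.frame(
      sample_name = samples$sample_name,
      nitrate = fmt_num(nut$nitrate, 4),
      phosphate = fmt_num(nut$phosphate, 4),
      stringsAsFactors = FALSE)
    if (null_rate > 0) {
      for (col in c("nitrate", "phosphate")) {
        drop <- runif(n_samples) < null_rate
        nutrients[[col]][drop] <- "NA"
      }
    }
    list(samples = samples, nutrients = nutrients)
  })

  expected <- list()
  expect_issue <- function(code, resource, row = NA_integer_,
                           column = NA_character_)
    expected[[length(expected) + 1L]] <<-
      data.frame(code = code, resource = resource, row = as.integer(row),
                 column = column, stringsAsFactors = FALSE)

  deleted <- vapply(injections, function(inj)
    identical(inj$kind, "delete_file"), logical(1))
  deleted_res <- vapply(injections[deleted], function(inj) inj$resource,
                        character(1))

  ## content-level injections: applied before checksumming so only the
  ## intended cell issue fires
  for (inj in injections) {
    kind <- inj$kind
    if (!kind %in% INJECTION_KINDS)
      stop_oceanpack("parameter", sprintf("unknown injection kind: %s", kind))
    if (kind %in% c("type_error", "out_of_range", "bad_format")) {
      res <- inj$resource
      if (res %in% deleted_res)
        stop_oceanpack("parameter",
                       sprintf("cannot inject into deleted resource %s", res))
      if (is.null(tabs[[res]]) || inj$row > n_samples ||
          !inj$field %in% names(tabs[[res]]))
        stop_oceanpack("parameter", "injection coordinates out of range")
      if (kind == "type_error") {
        tabs[[res]][[inj$field]][inj$row] <- "not_a_number"
        expect_issue("TYPE_ERROR", res, inj$row, inj$field)
      } else if (kind == "out_of_range") {
        tabs[[res]][[inj$field]][inj$row] <- inj$value %||% "150"
        expect_issue("CONSTRAINT_VIOLATION", res, inj$row, inj$field)
      } else {
        tabs[[res]][[inj$field]][inj$row] <- "16/07/2012"
        expect_issue("FORMAT_ERROR", res, inj$row, inj$field)
      }
    }
  }

  ## descriptor-level injections
  for (inj in injections) {
    if (inj$kind == "strip_annotation") {
      fs <- fields[[inj$resource]]
      i <- match(inj$field, vapply(fs, function(f) f$name, character(1)))
      if (is.na(i)) stop_oceanpack("parameter", "no such field to strip")
      slot <- switch(inj$member %||% "device",
                     rdf_type = "rdf_type", unit = "unit_rdf_type",
                     device = "measurement_source_rdf_type",
                     stop_oceanpack("parameter", "unknown triad member"))
      if (is.null(fields[[inj$resource]][[i]][[slot]]))
        stop_oceanpack("parameter", "annotation already absent")
      fields[[inj$resource]][[i]][[slot]] <- NULL
      expect_issue("MISSING_ANNOTATION", inj$resource, column = inj$field)
    } else if (inj$kind == "unknown_term") {
      fs <- fields[[inj$resource]]
      i <- match(inj$field, vapply(fs, function(f) f$name, character(1)))
      if (is.na(i)) stop_oceanpack("parameter", "no such field")
      fields[[inj$resource]][[i]]$rdf_type <- term_ref("ENVO:9999999")
      expect_issue("UNKNOWN_TERM", inj$resource, column = inj$field)
    }
  }

  ## write resources, checksum, write descriptor
  paths <- c(samples = "samples.tsv", nutrients = "nutrients.tsv")
  md5 <- character()
  for (res in names(tabs)) {
    write_tsv_text(tabs[[res]], file.path(dir, paths[[res]]))
    md5[[res]] <- unname(tools::md5sum(file.path(dir, paths[[res]])))
  }
  pkg <- package_descriptor(
    name = sprintf("synthetic-package-seed%d", seed),
    title = "Synthetic ontology-annotated data package",
    resources = lapply(names(tabs), function(res)
      resource_spec(res, paths[[res]], fields[[res]], md5 = md5[[res]])),
    licenses = list(list(name = "ODC-BY-1.0",
                         path = "https://opendatacommons.org/licenses/by/")),
    sources = list(list(title = "oceanpack synthetic fixture generator",
                        path = "")))
  save_descriptor(pkg, file.path(dir, "datapackage.json"))

  ## post-checksum injections
  for (inj in injections) {
    if (inj$kind == "corrupt_file") {
      if (inj$resource %in% deleted_res)
        stop_oceanpack("parameter",
                       sprintf("cannot corrupt deleted resource %s", inj$resource))
      if (!inj$resource %in% names(paths))
        stop_oceanpack("parameter", "no such resource to corrupt")
      flip_one_byte(file.path(dir, paths[[inj$resource]]))
      expect_issue("CHECKSUM_MISMATCH", inj$resource)
    } else if (inj$kind == "delete_file") {
      if (!inj$resource %in% names(paths))
        stop_oceanpack("parameter", "no such resource to delete")
      file.remove(file.path(dir, paths[[inj$resource]]))
      expect_issue("MISSING_FILE", inj$resource)
    }
  }

  both <- tabs$nutrients$nitrate != "NA" & tabs$nutrients$phosphate != "NA"
  invisible(list(
    seed = seed, n_samples = n_samples, dir = dir, descriptor = pkg,
    tables = tabs, injections = injections,
    nutrients_available = data.frame(sample = tabs$nutrients$sample_name,
                                     both_nutrients = both,
                                     stringsAsFactors = FALSE),
    expected_issues = if (length(expected)) do.call(rbind, expected) else
      data.frame(code = character(), resource = character(), row = integer(),
                 column = character(), stringsAsFactors = FALSE)))
}

#' Draw a random, mutually consistent injection set
#'
#' Samples `k` injections over distinct targets, avoiding contradictions
#' (no cell injection or corruption in a deleted resource, no duplicate
#' cell/field targets), for use with [generate_package()].
#'
#' @param n_samples Number of data rows in the target package.
#' @param k Number of injections (0-10 is the intended regime).
#' @param seed Integer seed.
#' @return List of injection records.
#' @export
sample_injections <- function(n_samples, k, seed = 1) {
  with_seed(seed, {
    pool <- list()
    for (row in seq_len(n_samples)) {
      pool[[length(pool) + 1L]] <- list(kind = "type_error",
                                        resource = "nutrients",
                                        row = row, field = "nitrate")
      pool[[length(pool) + 1L]] <- list(kind = "out_of_range",
                                        resource = "samples",
                                        row = row, field = "latitude")
      pool[[length(pool) + 1L]] <- list(kind = "bad_format",
                                        resource = "samples",
                                        row = row, field = "collection_date")
    }
    pool[[length(pool) + 1L]] <- list(kind = "strip_annotation",
                                      resource = "nutrients",
                                      field = "phosphate", member = "device")
    pool[[length(pool) + 1L]] <- list(kind = "strip_annotation",
                                      resource = "samples",
                                      field = "temperature", member = "unit")
    pool[[length(pool) + 1L]] <- list(kind = "unknown_term",
                                      resource = "samples",
                                      field = "env_material")
    pool[[length(pool) + 1L]] <- list(kind = "corrupt_file",
                                      resource = "samples")
    pool[[length(pool) + 1L]] <- list(kind = "corrupt_file",
                                      resource = "nutrients")
    pool[[length(pool) + 1L]] <- list(kind = "delete_file",
                                      resource = "nutrients")
    k <- min(k, length(pool))
    chosen <- pool[sample.int(length(pool), k)]
    ## consistency: a deleted resource admits no other injection
    del <- vapply(chosen, function(x) x$kind == "delete_file", logical(1))
    if (any(del)) {
      del_res <- vapply(chosen[del], function(x) x$resource, character(1))
      keep <- vapply(chosen, function(x)
        x$kind %in% c("delete_file", "strip_annotation", "unknown_term") ||
          !x$resource %in% del_res, logical(1))
      chosen <- chosen[keep]
    }
    chosen
  })
}

#' Generate a depth-structured community count matrix
#'
#' Relative abundances follow logistic-in-depth trends: taxon `j` has weight
#' `exp(sign_j * magnitude_j * z)` with `z` the depth scaled to \[-1, 1\]
#' over `depth_range`, renormalized across taxa; counts are multinomial
#' draws at per-sample totals. `n_shallow` samples get totals below 100000
#' reads to exercise the shallow-sample filter. The default taxa set mirrors
#' the North Pacific Subtropical Gyre cast of characters: low-light-adapted
#' picocyanobacteria and ammonia-oxidizing archaea increasing with depth,
#' high-light-adapted strains decreasing.
#'
#' @param n_samples Number of samples.
#' @param taxa_spec Data frame `name`, `sign` (-1/0/+1), `magnitude` (>= 0);
#'   needs >= 2 taxa, and nonzero effects must not all share one sign.
#' @param depth_range Depth span in meters (default 25-125 m).
#' @param reads_range Per-sample read totals for retained samples.
#' @param n_shallow Number of samples forced under 100000 reads.
#' @param seed Integer seed.
#' @return List with `counts` (a counts-mode `community_matrix`), `depth`
#'   (named vector), and `manifest` (taxa truth table, shallow sample
#'   names, parameters).
#' @export
generate_community_depth_data <- function(n_samples,
                                          taxa_spec = NULL,
                                          depth_range = c(25, 125),
                                          reads_range = c(120000, 400000),
                                          n_shallow = 0, seed = 1) {
  if (is.null(taxa_spec)) {
    taxa_spec <- data.frame(
      name = c("Prochlorococcus sp. MIT 0801",
               "Candidatus Nitrosopelagicus brevis",
               "Prochlorococcus sp. RS50",
               "Prochlorococcus sp. MIT 0604",
               "Prochlorococcus marinus",
               "Pelagibacter ubique"),
      sign = c(1, 1, -1, -1, -1, 0),
      magnitude = c(2, 1.5, 2, 1.5, 1, 0),
      stringsAsFactors = FALSE)
  }
  if (nrow(taxa_spec) < 2)
    stop_oceanpack("parameter", "need at least 2 taxa")
  eff <- taxa_spec$sign * taxa_spec$magnitude
  if (any(eff != 0) && (all(eff >= 0) || all(eff <= 0)))
    stop_oceanpack("parameter",
                   "nonzero depth effects must not all share one sign")
  if (n_shallow > n_samples)
    stop_oceanpack("parameter", "n_shallow exceeds n_samples")
  with_seed(seed, {
    depth <- runif(n_samples, depth_range[1], depth_range[2])
    z <- (depth - mean(depth_range)) / (diff(depth_range) / 2)
    totals <- round(runif(n_samples, reads_range[1], reads_range[2]))
    if (n_shallow > 0)
      totals[seq_len(n_shallow)] <- round(runif(n_shallow, 2e4, 9e4))
    probs <- exp(outer(z, eff))
    probs <- probs / rowSums(probs)
    counts <- t(vapply(seq_len(n_samples),
                       function(i) rmultinom(1, totals[i], probs[i, ])[, 1],
                       integer(nrow(taxa_spec))))
    dimnames(counts) <- list(sprintf("S%04d", seq_len(n_samples)),
                             taxa_spec$name)
    names(depth) <- rownames(counts)
    list(counts = community_matrix(counts, "counts"), depth = depth,
         manifest = list(seed = seed, taxa = taxa_spec,
                         depth_range = depth_range,
                         shallow_samples = rownames(counts)[totals < 1e5]))
  })
}
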