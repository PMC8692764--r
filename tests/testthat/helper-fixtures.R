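# Shared fixtures built in code.

bundled_graph <- function() load_term_table(oceanpack_term_table())

# A small hand-written descriptor exercising annotations, constraints,
# missing values, datetime formats and an unknown extension key.
fixture_descriptor_json <- function() {
  '{
    "name": "hot-surface-subset",
    "title": "Surface nutrient subset",
    "pm:portalVersion": "2.1",
    "resources": [
      {
        "name": "nutrients",
        "path": "nutrients.tsv",
        "md5": "00000000000000000000000000000000",
        "schema": {
          "missingValues": ["NA"],
          "fields": [
            {"name": "sample_name", "type": "string",
             "rdfType": "http://purl.obolibrary.org/obo/IAO_0020000"},
            {"name": "date", "type": "datetime", "format": "%Y-%m-%dT%H:%M:%SZ",
             "rdfType": "http://purl.obolibrary.org/obo/OBI_0001619"},
            {"name": "latitude", "type": "number",
             "constraints": {"minimum": -90, "maximum": 90},
             "rdfType": "http://purl.obolibrary.org/obo/OBI_0001620",
             "pm:unitRdfType": "http://purl.obolibrary.org/obo/UO_0000185",
             "pm:measurmentSourceRdfType": "http://purl.obolibrary.org/obo/OBI_0000968"},
            {"name": "nitrate", "type": "number",
             "constraints": {"minimum": 0, "maximum": 100},
             "rdfType": "http://purl.obolibrary.org/obo/ENVO_3100022",
             "pm:unitRdfType": "http://purl.obolibrary.org/obo/UO_0010004",
             "pm:measurementSourceRdfType": "http://purl.obolibrary.org/obo/OBI_0400115",
             "pm:searchable": true}
          ]
        }
      }
    ]
  }'
}

write_fixture_package <- function(dir, rows = c(
    "sample_name\tdate\tlatitude\tnitrate",
    "HOT001\t2012-07-16T10:30:00Z\t22.7500\t0.12",
    "HOT002\t2012-07-17T10:30:00Z\t22.7500\tNA",
    "HOT003\t2012-07-18T10:30:00Z\t22.7500\t1.05")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pkg <- load_descriptor(fixture_descriptor_json())
  writeLines(rows, file.path(dir, "nutrients.tsv"))
  pkg$resources[[1]]$md5 <- unname(tools::md5sum(file.path(dir, "nutrients.tsv")))
  save_descriptor(pkg, file.path(dir, "datapackage.json"))
  pkg
}

# tiny term graph from parallel vectors
mini_graph <- function(curies, labels = curies, parents = rep("", length(curies))) {
  load_term_table(data.frame(curie = curies, label = labels, parents = parents,
                             stringsAsFactors = FALSE))
}

# independent reachability oracle: recursive DFS over the parent lists
brute_ancestors <- function(parents, curie) {
  out <- character()
  visit <- function(x) {
    for (p in parents[[x]]) {
      if (!p %in% out && p %in% names(parents)) {
        out <<- c(out, p)
        visit(p)
      }
    }
  }
  visit(curie)
  sort(out)
}

# random parent-list DAG: node i may only point to earlier nodes
random_dag <- function(k, seed) {
  withr::with_seed(seed, {
    curies <- sprintf("TST:%07d", seq_len(k))
    parents <- lapply(seq_len(k), function(i) {
      if (i == 1) return(character())
      cand <- curies[seq_len(i - 1)]
      cand[runif(length(cand)) < 0.3]
    })
    names(parents) <- curies
    parents
  })
}

dag_to_table <- function(parents) {
  data.frame(curie = names(parents),
             label = names(parents),
             parents = vapply(parents, paste, character(1), collapse = "|"),
             stringsAsFactors = FALSE)
}

# canonical multiset representation of located issues
issue_multiset <- function(df) {
  sort(paste(df$code, df$resource,
             ifelse(is.na(df$row), "-", df$row),
             ifelse(is.na(df$column), "-", df$column), sep = "|"))
}
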