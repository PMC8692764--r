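make_two_packages <- function(root) {
  d1 <- file.path(root, "p1"); d2 <- file.path(root, "p2")
  m1 <- generate_package(d1, n_samples = 6, seed = 1, null_rate = 0.3)
  m2 <- generate_package(d2, n_samples = 6, seed = 2)
  list(pkgs = list(m1$descriptor, m2$descriptor), dirs = c(d1, d2),
       manifests = list(m1, m2))
}

test_that("attribute search honors subsumption and is a superset of exact search", {
  g <- bundled_graph()
  j <- '{"name":"chl","resources":[{"name":"r","path":"r.tsv","schema":{"fields":[
        {"name":"chl_a","type":"number",
         "rdfType":"http://purl.obolibrary.org/obo/ENVO_3100008"}]}}]}'
  pkg <- load_descriptor(j)
  hits <- search_attributes(list(pkg), g,
                            attribute_query("ENVO:3100036", include_descendants = TRUE))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$field, "chl_a")
  expect_false(hits$exact)
  expect_equal(nrow(search_attributes(list(pkg), g, "ENVO:3100036")), 0)
  expect_equal(nrow(search_attributes(list(), g, "ENVO:3100036")), 0)
  expect_error(search_attributes(list(pkg), g, "ENVO:0000001"),
               class = "oceanpack_unknown_term")
  # subsumption results always contain the exact results
  for (q in c("ENVO:3100008", "ENVO:3100036", "ENVO:3100022")) {
    exact <- search_attributes(list(pkg), g, q)
    sub <- search_attributes(list(pkg), g,
                             attribute_query(q, include_descendants = TRUE))
    expect_true(all(do.call(paste, exact[1:3]) %in% do.call(paste, sub[1:3])))
  }
})

test_that("harmonization joins packages with provenance and one unit per column", {
  g <- bundled_graph()
  root <- withr::local_tempdir()
  fx <- make_two_packages(root)
  attrs <- c("ENVO:3100022", "TEMP:0000001", "OBI:0001620")
  ht <- build_harmonized_table(fx$pkgs, fx$dirs, g, attrs)
  expect_s3_class(ht, "harmonized_table")
  expect_equal(names(ht$values), c("sample", attrs))
  # every non-null cell carries full provenance
  non_null <- sum(!is.na(as.matrix(ht$values[attrs])))
  expect_equal(non_null, nrow(ht$provenance))
  expect_true(all(!is.na(ht$provenance$package)))
  expect_true(all(!is.na(ht$provenance$field)))
  # conservation: contributions = kept cells + logged conflicts
  expect_equal(nrow(ht$provenance) + nrow(ht$conflicts), non_null + nrow(ht$conflicts))
  # both source packages contributed
  expect_setequal(unique(ht$provenance$package),
                  vapply(fx$pkgs, function(p) p$name, character(1)))
  # rebuilding from sources reproduces identical values
  ht2 <- build_harmonized_table(fx$pkgs, fx$dirs, g, attrs)
  expect_identical(ht$values, ht2$values)
})

test_that("unit conversion is applied towards the column target unit", {
  g <- bundled_graph()
  dir <- withr::local_tempdir()
  # one package reporting nitrate in nanomolar
  j <- sprintf('{"name":"nano","resources":[{"name":"r","path":"r.tsv","schema":{"fields":[
    {"name":"sample_name","type":"string","rdfType":"%s"},
    {"name":"nitrate","type":"number","rdfType":"%s","pm:unitRdfType":"%s"}]}}]}',
    curie_to_purl("IAO:0020000"), curie_to_purl("ENVO:3100022"),
    curie_to_purl("UO:0000065"))
  pkg <- load_descriptor(j)
  writeLines(c("sample_name\tnitrate", "X1\t1500"), file.path(dir, "r.tsv"))
  ht <- build_harmonized_table(list(pkg), dir, g, "ENVO:3100022",
                               target_units = c("ENVO:3100022" = "UO:0000064"))
  expect_equal(ht$values[["ENVO:3100022"]], 1.5)   # 1500 nM -> 1.5 uM
  expect_equal(unname(ht$units["ENVO:3100022"]), "UO:0000064")
  expect_equal(ht$provenance$original_unit, "UO:0000065")
})

test_that("co-selection counts match the generator's nutrient manifest", {
  g <- bundled_graph()
  root <- withr::local_tempdir()
  fx <- make_two_packages(root)
  attrs <- c("ENVO:3100022", "TEMP:0000001")
  ht <- build_harmonized_table(fx$pkgs[1], fx$dirs[1], g, attrs)
  flt <- filter_samples(ht, list(list(attribute = "ENVO:3100022", non_null = TRUE),
                                 list(attribute = "TEMP:0000001", non_null = TRUE)))
  expected <- sum(fx$manifests[[1]]$nutrients_available$both_nutrients)
  expect_equal(nrow(flt$values), expected)
  expect_equal(attr(flt, "removed"), nrow(ht$values) - expected)
  # empty predicate list is the identity
  expect_equal(nrow(filter_samples(ht, list())$values), nrow(ht$values))
  expect_error(filter_samples(ht, list(list(attribute = "ENVO:3100022",
                                            min = 5, max = 1))),
               class = "oceanpack_column_predicate")
  expect_error(filter_samples(ht, list(list(attribute = "TEMP:9999999",
                                            non_null = TRUE))),
               class = "oceanpack_missing_column")
})

test_that("environmental context attaches biome/feature/material with labels", {
  g <- bundled_graph()
  root <- withr::local_tempdir()
  fx <- make_two_packages(root)
  ht <- build_harmonized_table(fx$pkgs, fx$dirs, g, "ENVO:3100022")
  ht <- attach_env_context(ht, fx$pkgs, fx$dirs, g)
  ctx <- ht$context
  expect_equal(ctx$biome_label[1], "marine biome")
  expect_true(all(ctx$material_label == "sea water", na.rm = TRUE))
  expect_true(all(ctx$feature_known, na.rm = TRUE))
  feats <- unique(ctx$feature_label)
  expect_true(all(feats %in% c("deep chlorophyll maximum layer",
                               "marine mesopelagic zone", "sea surface layer")))
})

test_that("freshwater-context samples are separable from the marine pool", {
  g <- bundled_graph()
  rf <- generate_redfield_data(50, n_outliers = 2, seed = 4)
  expect_length(rf$manifest$outlier_rows, 2)
  fresh <- rf$data$biome == "ENVO:01000252"
  expect_equal(sum(fresh), 2)
  expect_equal(which(fresh), rf$manifest$outlier_rows)
  # the outliers sit in the deviating regime: high nitrate, ~zero phosphate
  expect_true(all(rf$data$nitrate[fresh] >= 37 & rf$data$nitrate[fresh] <= 40))
  expect_true(all(rf$data$phosphate[fresh] < 0.1))
})

test_that("climate zones partition [-90, 90] with poleward boundaries", {
  lats <- c(seq(-90, 90, by = 0.25), 23.5 - 1e-9, 66.5 - 1e-9,
            withr::with_seed(1, runif(500, -90, 90)))
  z <- climate_zone(lats)
  expect_false(any(is.na(z)))                      # total
  expect_equal(length(z), length(lats))            # exactly one zone each
  expect_equal(as.character(climate_zone(22.75)), "tropical")
  expect_equal(as.character(climate_zone(23.5)), "temperate")
  expect_equal(as.character(climate_zone(-70)), "polar")
  expect_equal(as.character(climate_zone(c(66.5, -66.5))), c("polar", "polar"))
  expect_error(climate_zone(91), class = "oceanpack_domain")
  expect_equal(unname(climate_zone_terms()["tropical"]), "ENVO:01000204")
  # zone <-> |lat| band agreement
  expect_true(all((abs(lats) < 23.5) == (z == "tropical")))
  expect_true(all((abs(lats) >= 66.5) == (z == "polar")))
})
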