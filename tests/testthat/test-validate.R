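test_that("transferability: presence and checksum of every resource", {
  dir <- withr::local_tempdir()
  pkg <- write_fixture_package(dir)
  rep <- verify_transferability(pkg, dir)
  expect_true(rep$pass)
  expect_equal(nrow(rep$issues), 0)
  # single appended byte -> exactly one CHECKSUM_MISMATCH
  cat("x", file = file.path(dir, "nutrients.tsv"), append = TRUE)
  rep2 <- verify_transferability(pkg, dir)
  expect_false(rep2$pass)
  expect_equal(rep2$issues$code, "CHECKSUM_MISMATCH")
  # absent file -> MISSING_FILE
  file.remove(file.path(dir, "nutrients.tsv"))
  rep3 <- verify_transferability(pkg, dir)
  expect_equal(rep3$issues$code, "MISSING_FILE")
})

test_that("an empty resource matches the reference MD5 of empty input", {
  # d41d...427e computed independently with a reference MD5 implementation
  j <- '{"name":"x","resources":[{"name":"r","path":"r.tsv",
        "md5":"d41d8cd98f00b204e9800998ecf8427e","schema":{"fields":[]}}]}'
  pkg <- load_descriptor(j)
  dir <- withr::local_tempdir()
  file.create(file.path(dir, "r.tsv"))
  expect_true(verify_transferability(pkg, dir)$pass)
})

test_that("cell validation: type, datetime format, inclusive range constraints", {
  dir <- withr::local_tempdir()
  pkg <- write_fixture_package(dir, rows = c(
    "sample_name\tdate\tlatitude\tnitrate",
    "S1\t2012-07-16T10:30:00Z\t91\t1.0",     # latitude out of range
    "S2\t16/07/2012\t-90\t2.0",              # bad datetime; boundary lat passes
    "S3\t2012-07-16T10:30:00Z\t90\tbogus",   # boundary lat passes; type error
    "S4\t2012-07-16T10:30:00Z\tbad\tNA"))    # unparseable lat; nitrate null
  res <- pkg$resources[[1]]
  tab <- load_resource(pkg, "nutrients", dir)
  iss <- validate_cells(tab, res$fields)
  expect_setequal(
    paste(iss$code, iss$row, iss$column),
    c("CONSTRAINT_VIOLATION 1 latitude", "FORMAT_ERROR 2 date",
      "TYPE_ERROR 3 nitrate", "TYPE_ERROR 4 latitude"))
  # spec/column mismatch reported as HEADER_MISMATCH
  mm <- validate_cells(tab, res$fields[1:2])
  expect_equal(mm$code, "HEADER_MISMATCH")
})

test_that("rows of declared missing values produce zero cell issues", {
  dir <- withr::local_tempdir()
  pkg <- write_fixture_package(dir, rows = c(
    "sample_name\tdate\tlatitude\tnitrate",
    "S1\t2012-07-16T10:30:00Z\t10\tNA",
    "S2\t2012-07-16T10:30:00Z\t11\tNA"))
  tab <- load_resource(pkg, "nutrients", dir)
  expect_equal(nrow(validate_cells(tab, pkg$resources[[1]]$fields)), 0)
})

test_that("annotation audit: incomplete triads warn, unknown terms error", {
  g <- bundled_graph()
  pkg <- load_descriptor(fixture_descriptor_json())
  expect_equal(nrow(audit_annotations(pkg, g)), 0)
  # numeric field lacking its device term -> one warning
  pkg$resources[[1]]$fields[[4]]$measurement_source_rdf_type <- NULL
  iss <- audit_annotations(pkg, g)
  expect_equal(iss$code, "MISSING_ANNOTATION")
  expect_equal(iss$severity, "warning")
  expect_equal(iss$column, "nitrate")
  # unresolvable CURIE -> error
  pkg$resources[[1]]$fields[[1]]$rdf_type <- term_ref("ENVO:9999999")
  iss2 <- audit_annotations(pkg, g)
  expect_true(any(iss2$code == "UNKNOWN_TERM" & iss2$severity == "error"))
  # warnings alone keep the package passing; errors fail it
  dir <- withr::local_tempdir()
  write_fixture_package(dir)
  pkg3 <- load_descriptor(file.path(dir, "datapackage.json"))
  pkg3$resources[[1]]$fields[[4]]$measurement_source_rdf_type <- NULL
  rep <- validate_package(pkg3, dir, g)
  expect_true(rep$pass)
  expect_equal(sum(rep$counts), 1)
})

test_that("validate_package reports exactly the injected issue multiset", {
  g <- bundled_graph()
  dir <- withr::local_tempdir()
  inj <- list(
    list(kind = "type_error", resource = "nutrients", row = 2, field = "nitrate"),
    list(kind = "out_of_range", resource = "samples", row = 5, field = "latitude"),
    list(kind = "bad_format", resource = "samples", row = 1, field = "collection_date"),
    list(kind = "strip_annotation", resource = "samples", field = "temperature",
         member = "unit"),
    list(kind = "unknown_term", resource = "samples", field = "env_material"),
    list(kind = "corrupt_file", resource = "nutrients"))
  man <- generate_package(file.path(dir, "p"), n_samples = 6, seed = 3,
                          injections = inj)
  rep <- validate_package(
    load_descriptor(file.path(dir, "p", "datapackage.json")),
    file.path(dir, "p"), g)
  expect_identical(issue_multiset(rep$issues),
                   issue_multiset(man$expected_issues))
  # idempotence: a second run yields an identical report
  rep2 <- validate_package(
    load_descriptor(file.path(dir, "p", "datapackage.json")),
    file.path(dir, "p"), g)
  expect_identical(rep$issues, rep2$issues)
  # deterministic ordering: resource, then row, then column, then code
  expect_false(is.unsorted(order(rep$issues$resource)))
})

test_that("adding an injection never removes previously reported issues", {
  g <- bundled_graph()
  base <- list(list(kind = "out_of_range", resource = "samples", row = 2,
                    field = "latitude"))
  more <- c(base, list(list(kind = "type_error", resource = "nutrients",
                            row = 3, field = "phosphate")))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_package(d1, n_samples = 5, seed = 8, injections = base)
  generate_package(d2, n_samples = 5, seed = 8, injections = more)
  r1 <- validate_package(load_descriptor(file.path(d1, "datapackage.json")), d1, g)
  r2 <- validate_package(load_descriptor(file.path(d2, "datapackage.json")), d2, g)
  expect_true(all(issue_multiset(r1$issues) %in% issue_multiset(r2$issues)))
})

test_that("swapped latitude/longitude shows up as a latitude range violation", {
  g <- bundled_graph()
  dir <- withr::local_tempdir()
  man <- generate_package(dir, n_samples = 4, seed = 2, injections = list(
    list(kind = "out_of_range", resource = "samples", row = 3,
         field = "latitude", value = "150")))
  rep <- validate_package(load_descriptor(file.path(dir, "datapackage.json")),
                          dir, g)
  expect_equal(rep$issues$code, "CONSTRAINT_VIOLATION")
  expect_equal(rep$issues$column, "latitude")
  expect_equal(rep$issues$row, 3L)
})
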