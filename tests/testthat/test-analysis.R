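test_that("OLS recovers exact parameters on noiseless linear data", {
  f <- ols_fit(c(16, 32, 48), c(1, 2, 3))
  expect_equal(f$slope, 0.0625)
  expect_equal(f$intercept, 0)
  x <- 1:10
  f2 <- ols_fit(x, x)
  expect_equal(f2$slope, 1)
  expect_equal(f2$r_squared, 1)
  expect_error(ols_fit(rep(2, 5), 1:5), class = "oceanpack_degenerate_predictor")
  expect_error(ols_fit(1:3, 1:4), class = "oceanpack_shape")
  expect_error(ols_fit(c(1, NA, 3), 1:3), class = "oceanpack_shape")
})

test_that("slope recovery tightens with sample size on the nutrient generator", {
  err_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      rf <- generate_redfield_data(n, noise_sd = 0.2, seed = s)
      ols_fit(rf$data$nitrate, rf$data$phosphate)$slope
    }, numeric(1))) - 1 / 16
  }
  expect_lt(abs(err_at(100, 1:30)), 0.0015)
  expect_lt(abs(err_at(10000, 1:5)), 0.001)
})

test_that("the mean recovered slope sits within the estimator's sampling spread", {
  slopes <- vapply(1:100, function(s) {
    rf <- generate_redfield_data(1000, noise_sd = 0.2, seed = s)
    ols_fit(rf$data$nitrate, rf$data$phosphate)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1 / 16), 2 * sd(slopes))
})

test_that("Spearman handles ties by average rank and monotone transforms", {
  expect_equal(spearman_rho(1:3, c(1, 4, 9)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)
  # hand-computed oracle: ranks (1, 2.5, 2.5, 4) vs (1, 2, 3, 4),
  # Pearson of the rank vectors = 1.5 / sqrt(2.5)
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 2, 3, 4)), 1.5 / sqrt(2.5))
  # invariance under strictly monotone transforms of either argument
  x <- withr::with_seed(7, runif(50)); y <- withr::with_seed(8, runif(50))
  rho <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(3 * x), y), rho)
  expect_equal(spearman_rho(x, y^3 + 2), rho)
  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "oceanpack_undefined_correlation")
  expect_error(spearman_rho(1:2, 1:2), class = "oceanpack_shape")
})

test_that("facet summary crosses environmental feature with climate zone", {
  values <- data.frame(
    sample = sprintf("S%02d", 1:12),
    "ENVO:09200014" = c(2, 3, 4, 25, 26, 27, 5, 6, 7, 20, 21, 22),
    "OBI:0001620" = c(rep(70, 3), rep(10, 3), rep(-80, 3), rep(40, 3)),
    check.names = FALSE, stringsAsFactors = FALSE)
  ctx <- data.frame(
    sample = values$sample,
    feature = rep(c("ENVO:01001581", "ENVO:00000213"), each = 6),
    feature_label = rep(c("sea surface layer", "marine mesopelagic zone"), each = 6),
    feature_known = TRUE, stringsAsFactors = FALSE)
  ht <- structure(list(values = values,
                       units = c("ENVO:09200014" = "UO:0000027",
                                 "OBI:0001620" = "UO:0000185"),
                       provenance = NULL, conflicts = NULL, context = ctx),
                  class = "harmonized_table")
  out <- facet_summary(ht, "ENVO:09200014", "OBI:0001620")
  expect_equal(nrow(out), 4)   # 2 features x 2 zones, all occupied
  key <- paste(out$feature, out$zone)
  expect_equal(out$mean[key == "ENVO:01001581 polar"], 3)
  expect_equal(out$mean[key == "ENVO:01001581 tropical"], 26)
  expect_equal(out$mean[key == "ENVO:00000213 polar"], 6)
  expect_equal(out$mean[key == "ENVO:00000213 temperate"], 21)
  expect_equal(out$n, rep(3L, 4))
  expect_equal(out$sd, rep(1, 4))
  # singleton cell: sd reported absent
  ht1 <- ht; ht1$values <- ht1$values[1, ]; ht1$context <- ht1$context[1, ]
  out1 <- facet_summary(ht1, "ENVO:09200014", "OBI:0001620")
  expect_equal(out1$n, 1L)
  expect_true(is.na(out1$sd))
  # no context -> empty summary plus warning
  ht0 <- ht; ht0$context <- NULL
  expect_warning(out0 <- facet_summary(ht0, "ENVO:09200014", "OBI:0001620"),
                 class = "oceanpack_no_context")
  expect_equal(nrow(out0), 0)
})

test_that("relative abundance drops contaminants then shallow samples", {
  m <- community_matrix(matrix(c(2, 2, 150000, 50000, 60000, 40000),
                               nrow = 2,
                               dimnames = list(c("deep", "shallow"),
                                               c("a", "b", "c"))), "counts")
  # row "deep": 2 + 150000 + 60000; row "shallow": 2 + 50000 + 40000
  ra <- relative_abundance(m, min_reads = 1e5)
  expect_equal(rownames(ra), c("deep", "shallow")[rowSums(m) >= 1e5])
  expect_equal(unname(rowSums(ra)), rep(1, nrow(ra)), tolerance = 1e-9)
  # dropping the dominant contaminant changes who survives the filter
  ra2 <- relative_abundance(m, min_reads = 1e5, contaminants = "c")
  expect_false("c" %in% colnames(ra2))
  expect_equal(rownames(ra2), "deep")
  expect_equal(attr(ra2, "dropped_samples"), "shallow")
  expect_equal(unname(unclass(relative_abundance(
    community_matrix(matrix(c(2, 2), 1, dimnames = list("s", c("a", "b"))),
                     "counts"), min_reads = 1)[1, ])), c(0.5, 0.5))
  expect_error(relative_abundance(m, min_reads = 1e9),
               class = "oceanpack_empty_matrix")
})

test_that("Bray-Curtis has the right values, symmetry, range and diagonal", {
  m <- rbind(a = c(6, 2), b = c(2, 2), c = c(6, 2))
  D <- as.matrix(bray_curtis(m))
  expect_equal(D["a", "b"], 4 / 12)          # direct formula evaluation
  expect_equal(D["a", "c"], 0)               # identical rows
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_true(isSymmetric(D))
  disjoint <- rbind(c(1, 1, 0), c(0, 0, 1))
  expect_equal(as.vector(bray_curtis(disjoint)), 1)
  r <- withr::with_seed(5, matrix(runif(60), 10))
  Dr <- as.matrix(bray_curtis(r))
  expect_true(all(Dr >= 0 & Dr <= 1))
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 1))),
               class = "oceanpack_undefined_distance")
})

test_that("dbRDA on Euclidean distances equals the univariate linear-model R^2", {
  y <- withr::with_seed(10, rnorm(6))
  x <- withr::with_seed(11, rnorm(6))
  r <- oceanpack::dbrda(dist(y), x, n_perm = 99, seed = 1)
  expect_equal(r$r_squared, summary(lm(y ~ x))$r.squared, tolerance = 1e-9)
})

test_that("dbRDA agrees with the vegan permutational ANOVA on Bray-Curtis", {
  cm <- generate_community_depth_data(18, seed = 21)
  ra <- relative_abundance(cm$counts)
  D <- bray_curtis(ra)
  ours <- oceanpack::dbrda(D, cm$depth, species = ra, n_perm = 199, seed = 5)
  ref <- vegan::adonis2(D ~ depth, data = data.frame(depth = cm$depth),
                        permutations = 199)
  expect_equal(ours$r_squared, ref$R2[1], tolerance = 1e-9)
  # coefficient signs read as increase/decrease with depth
  truth <- cm$manifest$taxa
  nz <- truth$sign != 0
  expect_equal(sign(ours$coefficients[truth$name[nz]]),
               setNames(truth$sign[nz], truth$name[nz]))
})

test_that("permutation p-values are seed-reproducible and never zero", {
  cm <- generate_community_depth_data(14, seed = 31)
  ra <- relative_abundance(cm$counts)
  D <- bray_curtis(ra)
  r1 <- oceanpack::dbrda(D, cm$depth, n_perm = 199, seed = 7)
  r2 <- oceanpack::dbrda(D, cm$depth, n_perm = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  expect_error(oceanpack::dbrda(D, rep(1, nrow(as.matrix(D))), n_perm = 99),
               class = "oceanpack_degenerate_covariate")
  expect_error(oceanpack::dbrda(matrix(1:4, 2), c(1, 2), n_perm = 99),
               class = "oceanpack_shape")
})

test_that("top coefficients rank by absolute value with lexical tie-breaks", {
  r <- structure(list(coefficients = c(t1 = 0.5, t2 = -0.9, t3 = 0.1)),
                 class = "dbrda_result")
  expect_equal(top_coefficients(r, 2), c("t2", "t1"))
  expect_equal(top_coefficients(r, 10), c("t2", "t1", "t3"))
  tie <- structure(list(coefficients = c(b = -0.4, a = 0.4, c = 0.2)),
                   class = "dbrda_result")
  expect_equal(top_coefficients(tie, 2), c("a", "b"))
})
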