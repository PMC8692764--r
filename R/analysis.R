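## Statistical layer -----------------------------------------------------
##
## The downstream analyses a harmonized table enables: nutrient
## stoichiometry regression (the ~16:1 nitrate:phosphate ratio translates to
## an expected phosphate-on-nitrate slope of 1/16 = 0.0625), rank
## correlation, climate-zone faceting, and community ordination against
## depth (relative abundance -> Bray-Curtis -> permutational dbRDA with
## per-taxon coefficients).

#' Ordinary least squares fit
#'
#' Fits `y ~ x` by least squares. In the nutrient-stoichiometry use the
#' response is phosphate and the predictor nitrate, so the slope is directly
#' comparable to the inverse Redfield ratio 1/16.
#'
#' @param x,y Numeric vectors of equal length (>= 2), no missing values.
#' @return An `ols_fit`: `slope`, `intercept`, `r_squared`, `n`.
#' @examples
#' ols_fit(c(16, 32, 48), c(1, 2, 3))  # slope 1/16
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y))
    stop_oceanpack("shape", sprintf("length(x) = %d but length(y) = %d",
                                    length(x), length(y)))
  if (length(x) < 2L)
    stop_oceanpack("shape", "need at least 2 observations")
  if (anyNA(x) || anyNA(y))
    stop_oceanpack("shape", "missing values are not allowed; filter first")
  if (stats::var(x) == 0)
    stop_oceanpack("degenerate_predictor", "x is constant")
  fit <- stats::lm(y ~ x)
  ## R^2 from sums of squares directly; summary.lm warns on exact fits
  r2 <- if (stats::var(y) == 0) 1 else
    1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(slope = unname(coef(fit)[["x"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r_squared = r2,
         n = length(x)),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<OLS fit (n = %d): y = %.*g + %.*g x, R^2 = %.*g>\n",
              x$n, digits, x$intercept, digits, x$slope, digits, x$r_squared))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive their mean
#' rank).
#'
#' @param x,y Numeric vectors of equal length (>= 3), no missing values.
#' @return The correlation coefficient rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_oceanpack("shape", "need equal-length vectors with >= 3 observations")
  if (anyNA(x) || anyNA(y))
    stop_oceanpack("shape", "missing values are not allowed; filter first")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_oceanpack("undefined_correlation",
                   "correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Summarize an attribute by environmental feature and climate zone
#'
#' Cross-tabulates one harmonized attribute over the ENVO environmental
#' feature of each sample and its latitude-derived climate zone, reporting
#' n, mean and sd per occupied cell (sd is `NA` for singleton cells; empty
#' cells are omitted).
#'
#' @param table A `harmonized_table` with environmental context attached.
#' @param attribute Attribute CURIE to summarize.
#' @param latitude Attribute CURIE (or column name) holding latitude.
#' @return Data frame `feature`, `feature_label`, `zone`, `n`, `mean`, `sd`.
#' @export
facet_summary <- function(table, attribute, latitude) {
  for (col in c(attribute, latitude))
    if (!col %in% names(table$values))
      stop_oceanpack("missing_column", sprintf("no attribute column %s", col))
  if (is.null(table$context) || all(is.na(table$context$feature))) {
    warn_oceanpack("no_context", "no environmental feature context on this table")
    return(data.frame(feature = character(), feature_label = character(),
                      zone = character(), n = integer(), mean = numeric(),
                      sd = numeric(), stringsAsFactors = FALSE))
  }
  ctx <- table$context[match(table$values$sample, table$context$sample), ]
  v <- table$values[[attribute]]
  lat <- table$values[[latitude]]
  ok <- !is.na(v) & !is.na(lat) & !is.na(ctx$feature)
  if (!any(ok))
    return(data.frame(feature = character(), feature_label = character(),
                      zone = character(), n = integer(), mean = numeric(),
                      sd = numeric(), stringsAsFactors = FALSE))
  zone <- as.character(climate_zone(lat[ok]))
  key <- data.frame(feature = ctx$feature[ok],
                    feature_label = ctx$feature_label[ok],
                    zone = zone, value = v[ok], stringsAsFactors = FALSE)
  parts <- split(key, list(key$feature, key$zone), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) data.frame(
    feature = d$feature[1], feature_label = d$feature_label[1],
    zone = d$zone[1], n = nrow(d), mean = mean(d$value),
    sd = if (nrow(d) > 1) sd(d$value) else NA_real_,
    stringsAsFactors = FALSE)))
  out <- out[order(out$feature, out$zone), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## -- community matrices --------------------------------------------------

#' Construct a community matrix
#'
#' @param m Numeric samples x taxa matrix, non-negative, with dimnames.
#' @param mode `"counts"` (raw reads) or `"relative"` (rows sum to 1).
#' @return A `community_matrix` (the matrix, with `mode` and per-sample
#'   `totals` attributes).
#' @export
community_matrix <- function(m, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (any(m < 0)) stop_oceanpack("shape", "community matrix entries must be >= 0")
  if (is.null(rownames(m))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("taxon", seq_len(ncol(m)))
  if (mode == "relative") {
    s <- rowSums(m)
    if (any(abs(s - 1) > 1e-9))
      stop_oceanpack("shape", "relative-mode rows must sum to 1")
  }
  structure(m, mode = mode, totals = rowSums(m), class = c("community_matrix", "matrix"))
}

#' Normalize counts to relative abundance
#'
#' Contaminant taxa are dropped first; then samples whose remaining read
#' total falls below `min_reads` (shallow samples) are removed; remaining
#' rows are divided by their totals.
#'
#' @param counts A counts-mode `community_matrix`.
#' @param min_reads Minimum per-sample read total (default 100000).
#' @param contaminants Character vector of taxon names to drop.
#' @return A relative-mode `community_matrix`; dropped sample names are in
#'   the `dropped_samples` attribute.
#' @export
relative_abundance <- function(counts, min_reads = 1e5,
                               contaminants = character()) {
  stopifnot(inherits(counts, "community_matrix"))
  if (!identical(attr(counts, "mode"), "counts"))
    stop_oceanpack("shape", "relative_abundance expects a counts-mode matrix")
  m <- unclass(counts)
  attr(m, "mode") <- NULL; attr(m, "totals") <- NULL
  m <- m[, setdiff(colnames(m), contaminants), drop = FALSE]
  totals <- rowSums(m)
  keep <- totals >= min_reads
  if (!any(keep))
    stop_oceanpack("empty_matrix",
                   sprintf("all %d samples fall below %g reads", nrow(m), min_reads))
  dropped <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE] / totals[keep]
  out <- community_matrix(m, mode = "relative")
  attr(out, "totals") <- totals[keep]
  attr(out, "dropped_samples") <- dropped
  out
}

#' Bray-Curtis dissimilarity
#'
#' `D[i, j] = sum(|x_i - x_j|) / sum(x_i + x_j)`: symmetric, zero diagonal,
#' bounded in \[0, 1\].
#'
#' @param m A `community_matrix` (counts or relative) or plain non-negative
#'   matrix.
#' @return A `dist` object.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop_oceanpack("shape", "entries must be >= 0")
  if (sum(rowSums(m) == 0) >= 2L)
    stop_oceanpack("undefined_distance",
                   "two all-zero rows have undefined Bray-Curtis distance")
  vegan::vegdist(m, method = "bray")
}

## -- distance-based redundancy analysis ---------------------------------

#' Permutational dbRDA of a distance matrix against one covariate
#'
#' Partitions the variance of a (squared, Gower double-centered) distance
#' matrix on a single centered covariate, in the manner of permutational
#' multivariate ANOVA: `R^2 = (x' G x / x'x) / trace(G)` with
#' `G = -1/2 J D^2 J`. Significance comes from `n_perm` random permutations
#' of the covariate under an explicit seed, with the `(b + 1) / (n_perm + 1)`
#' p-value estimator so p is never exactly zero. When a species matrix is
#' supplied, per-taxon coefficients are the least-squares slopes of each
#' centered taxon abundance on the centered covariate — the coefficient
#' matrix convention of the permutational ANOVA implementation the field
#' uses, whose sign reads as increase (+) or decrease (-) with the
#' covariate.
#'
#' @param d Distance matrix (`dist` or square symmetric matrix).
#' @param covariate Numeric covariate (e.g. depth in meters), one value per
#'   sample.
#' @param species Optional samples x taxa `community_matrix` (or matrix) for
#'   coefficient extraction.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return A `dbrda_result`: `r_squared`, `p_value`, `coefficients` (named,
#'   or `NULL`), `n`, `n_perm`, `seed`.
#' @export
dbrda <- function(d, covariate, species = NULL, n_perm = 999, seed = 1) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12))
    stop_oceanpack("shape", "distance matrix must be square and symmetric")
  n <- nrow(D)
  if (length(covariate) != n)
    stop_oceanpack("shape", "covariate length must equal the number of samples")
  if (n_perm < 99) stop_oceanpack("shape", "need n_perm >= 99")
  if (stats::var(covariate) == 0)
    stop_oceanpack("degenerate_covariate", "covariate is constant")
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  ss_total <- sum(diag(G))
  r2_for <- function(x) {
    xc <- x - mean(x)
    (drop(crossprod(xc, G %*% xc)) / sum(xc^2)) / ss_total
  }
  r2 <- r2_for(covariate)
  b <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) r2_for(covariate[sample.int(n)]) >= r2,
               logical(1)))
  })
  coefs <- NULL
  if (!is.null(species)) {
    Y <- as.matrix(species)
    if (nrow(Y) != n)
      stop_oceanpack("shape", "species matrix rows must match samples")
    xc <- covariate - mean(covariate)
    Yc <- sweep(Y, 2, colMeans(Y))
    coefs <- drop(crossprod(Yc, xc)) / sum(xc^2)
    names(coefs) <- colnames(Y)
  }
  structure(
    list(r_squared = r2, p_value = (b + 1) / (n_perm + 1),
         coefficients = coefs, n = n, n_perm = n_perm, seed = seed),
    class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("<dbRDA (n = %d): R^2 = %.4f, p = %.4g (%d permutations, seed %d)>\n",
              x$n, x$r_squared, x$p_value, x$n_perm, x$seed))
  if (!is.null(x$coefficients))
    cat(sprintf("  %d per-taxon coefficient(s); strongest: %s\n",
                length(x$coefficients),
                paste(top_coefficients(x, min(3, length(x$coefficients))),
                      collapse = ", ")))
  invisible(x)
}

#' Rank taxa by absolute dbRDA coefficient
#'
#' @param r A `dbrda_result` with coefficients.
#' @param k Number of taxa to return.
#' @return Character vector of taxon names, decreasing `|coefficient|`, ties
#'   broken by taxon name.
#' @export
top_coefficients <- function(r, k) {
  stopifnot(inherits(r, "dbrda_result"), k >= 1)
  if (is.null(r$coefficients))
    stop_oceanpack("shape", "dbrda result has no species coefficients")
  o <- order(-abs(r$coefficients), names(r$coefficients))
  names(r$coefficients)[o][seq_len(min(k, length(r$coefficients)))]
}
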