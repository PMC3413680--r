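# Pearson correlation over experiment subsets, correlation significance,
# and the A/B correlation sets that drive the selection objective:
#   A = correlations of within-category gene pairs (upper triangle only);
#   B = correlations of category-vs-background pairs.
# Background-vs-background pairs are never used.

#' Pearson correlation on pairwise-complete observations
#'
#' @param x,y Numeric vectors of equal length; `NA` marks missing values.
#' @return The sample Pearson correlation computed over positions where
#'   both vectors are observed, or `NA` (the "undefined correlation"
#'   signal) when fewer than 3 complete positions remain or either vector
#'   is constant on them.  Callers count `NA`s as dropped pairs rather
#'   than treating them as errors.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  r <- stats::cor(x, y)
  min(1, max(-1, r))
}

#' Two-sided p-value of a Pearson correlation
#'
#' Uses the t-transform: `t = r * sqrt((n - 2) / (1 - r^2))` follows a
#' Student t distribution with `n - 2` degrees of freedom under the
#' bivariate-normal null.  `|r| = 1` returns 0.
#'
#' @param r Correlation value(s) in `[-1, 1]`; vectorized.
#' @param n_arrays Number of observations the correlation was computed
#'   over (profile vector length); must be at least 3.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
correlation_pvalue <- function(r, n_arrays) {
  if (n_arrays < 3L) stop("n_arrays must be >= 3, got ", n_arrays)
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  r <- pmin(1, pmax(-1, r))
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) == 1
  p[exact] <- 0
  mid <- !is.na(r) & !exact
  tval <- r[mid] * sqrt((n_arrays - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * stats::pt(abs(tval), df = n_arrays - 2, lower.tail = FALSE)
  p
}

#' Fisher z confidence bounds for a correlation
#'
#' The interval is computed on the z scale, `z = atanh(r)`, which is
#' approximately normal with variance `1 / (n - 3)`, and mapped back
#' through `tanh`.
#'
#' @param r Correlation in `(-1, 1)`.
#' @param n_arrays Number of observations; must be at least 4.
#' @param confidence Coverage probability in `(0, 1)`, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
fisher_bounds <- function(r, n_arrays, confidence = 0.95) {
  if (n_arrays < 4L) stop("n_arrays must be >= 4, got ", n_arrays)
  stopifnot(abs(r) < 1, confidence > 0, confidence < 1)
  q <- stats::qnorm(1 - (1 - confidence) / 2)
  z <- atanh(r)
  half <- q * sqrt(1 / (n_arrays - 3))
  c(lower = tanh(z - half), upper = tanh(z + half))
}

#' Restrict a collection's matrix to the arrays of an experiment subset
#'
#' Correlation over an experiment subset is Pearson correlation over the
#' *concatenated* arrays of its member experiments (profiles get longer as
#' experiments are added), not an average of per-experiment correlations.
#'
#' @param collection An `expression_collection`.
#' @param experiment_subset Character vector of experiment ids.
#' @return The expression matrix restricted to the subset's arrays, in the
#'   collection's array order.
#' @export
concatenate_profiles <- function(collection, experiment_subset) {
  cols <- subset_arrays(collection, experiment_subset)
  collection$matrix[, cols, drop = FALSE]
}

#' Array ids belonging to an experiment subset
#' @param collection An `expression_collection`.
#' @param experiment_subset Character vector of experiment ids.
#' @return Character vector of array ids in the collection's array order.
#' @export
subset_arrays <- function(collection, experiment_subset) {
  if (!length(experiment_subset)) stop("experiment subset is empty")
  known <- experiment_ids(collection)
  unknown <- setdiff(experiment_subset, known)
  if (length(unknown)) {
    stop("unknown experiment id: ", paste(unknown, collapse = ", "))
  }
  map <- collection$experiments
  keep <- map$array_id[map$experiment_id %in% experiment_subset]
  colnames(collection$matrix)[colnames(collection$matrix) %in% keep]
}

# Row-standardize a genes x arrays matrix so that tcrossprod() yields
# Pearson correlations.  Rows with zero variance become all-NA.
.std_rows <- function(X) {
  X <- X - rowMeans(X)
  ss <- sqrt(rowSums(X^2))
  ss[ss == 0] <- NA_real_
  X / ss
}

# Correlation matrices A (category x category) and B (category x background)
# over the concatenated arrays of an experiment subset.  Entries are NA when
# the pair has < 3 pairwise-complete positions or a constant profile.
.cor_matrices <- function(collection, experiment_subset, partition) {
  cols <- subset_arrays(collection, experiment_subset)
  if (length(cols) < 3L) {
    stop("experiment subset spans only ", length(cols), " arrays; need >= 3")
  }
  M <- collection$matrix
  Xc <- M[partition$category, cols, drop = FALSE]
  Xb <- M[partition$background, cols, drop = FALSE]
  if (!anyNA(Xc) && !anyNA(Xb)) {
    Zc <- .std_rows(Xc)
    Zb <- .std_rows(Xb)
    A <- tcrossprod(Zc)
    B <- tcrossprod(Zc, Zb)
  } else {
    A <- suppressWarnings(stats::cor(t(Xc), use = "pairwise.complete.obs"))
    B <- suppressWarnings(stats::cor(t(Xc), t(Xb), use = "pairwise.complete.obs"))
    Oc <- !is.na(Xc); Ob <- !is.na(Xb)
    A[tcrossprod(Oc * 1) < 3] <- NA_real_
    B[tcrossprod(Oc * 1, Ob * 1) < 3] <- NA_real_
  }
  A[!is.na(A)] <- pmin(1, pmax(-1, A[!is.na(A)]))
  B[!is.na(B)] <- pmin(1, pmax(-1, B[!is.na(B)]))
  list(A = A, B = B, n_arrays = length(cols))
}

#' Build the A/B correlation sets for an experiment subset
#'
#' `a_values` are the correlations of all unordered within-category gene
#' pairs (the upper triangle of the category correlation matrix, diagonal
#' excluded); `b_values` are the correlations of all (category, background)
#' pairs.  Pairs whose correlation is undefined (fewer than 3 complete
#' positions, or a constant profile) are counted in `dropped_pairs` and
#' omitted.
#'
#' @param collection An `expression_collection`.
#' @param experiment_subset Character vector of experiment ids; their
#'   concatenated arrays must number at least 3.
#' @param partition A `gene_partition`.
#' @return An object of class `correlation_sets` with elements `a_values`,
#'   `b_values`, `n_arrays`, `dropped_pairs`.
#' @export
build_correlation_sets <- function(collection, experiment_subset, partition) {
  cm <- .cor_matrices(collection, experiment_subset, partition)
  a <- cm$A[upper.tri(cm$A)]
  b <- as.vector(cm$B)
  dropped <- sum(is.na(a)) + sum(is.na(b))
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) && !length(b)) stop("all gene pairs have undefined correlation")
  structure(list(a_values = a, b_values = b, n_arrays = cm$n_arrays,
                 dropped_pairs = dropped),
            class = "correlation_sets")
}

#' Keep only statistically significant correlations
#'
#' Filters a vector of correlation values by their two-sided t-transform
#' p-value.  Used when comparing correlation distributions across
#' experiment subsets of different sizes, where longer profile vectors
#' make small correlations significant: filtering puts subsets on a common
#' footing.
#'
#' @param values Numeric vector of correlations.
#' @param n_arrays Profile length the correlations were computed over.
#' @param alpha Significance level in `(0, 1)`, default 0.05.
#' @return The subset of `values` with `correlation_pvalue < alpha`.
#' @export
filter_significant <- function(values, n_arrays, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  values[correlation_pvalue(values, n_arrays) < alpha]
}
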