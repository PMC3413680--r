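# Synthetic expression collections with planted relevant experiments.
#
# Generative model (Gaussian latent plus noise): in a *relevant* experiment
# every category gene observes, per array, a shared latent signal
# s ~ N(0, signal_sd^2) plus i.i.d. noise N(0, noise_sd^2); in irrelevant
# experiments category genes are pure noise.  Background genes are grouped
# into independent co-expression blocks (emulating genes annotated to other
# terms): each block shares its own per-array latent in every experiment.
# The single effect size is the ratio signal_sd / noise_sd.

#' Specification of a synthetic expression collection
#'
#' Defaults emulate a modest microarray compendium with a planted truth:
#' 40 category genes, 200 background genes in blocks of 10, and 20
#' experiments of 6 arrays each of which the first 4 carry the category
#' signal, at effect size `signal_sd / noise_sd = 2` (a strongly activated
#' process against unit measurement noise).
#'
#' @param n_category_genes Number of category genes, default 40.
#' @param n_background_genes Number of background genes, default 200.
#' @param n_relevant Number of experiments carrying the planted category
#'   signal, default 4.
#' @param n_irrelevant Number of pure-noise experiments, default 16.
#' @param arrays_per_experiment Arrays per experiment (at least 3),
#'   default 6.
#' @param signal_sd Standard deviation of the shared latent signal,
#'   default 2.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise
#'   (must be positive), default 1.
#' @param background_block_size Genes per background co-expression block,
#'   default 10.
#' @param rng_seed Integer seed; generation is fully deterministic given
#'   the spec.
#' @param experiments Optional data.frame with columns `experiment_id`,
#'   `n_arrays`, `relevant` overriding the
#'   `n_relevant`/`n_irrelevant`/`arrays_per_experiment` shortcut.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_category_genes = 40L, n_background_genes = 200L,
                           n_relevant = 4L, n_irrelevant = 16L,
                           arrays_per_experiment = 6L,
                           signal_sd = 2, noise_sd = 1,
                           background_block_size = 10L,
                           rng_seed = 1L, experiments = NULL) {
  if (is.null(experiments)) {
    n_exp <- n_relevant + n_irrelevant
    stopifnot(n_exp >= 1L, arrays_per_experiment >= 3L)
    experiments <- data.frame(
      experiment_id = sprintf("E%02d", seq_len(n_exp)),
      n_arrays = rep.int(as.integer(arrays_per_experiment), n_exp),
      relevant = seq_len(n_exp) <= n_relevant,
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("experiment_id", "n_arrays", "relevant") %in% names(experiments)),
            all(experiments$n_arrays >= 3L),
            !anyDuplicated(experiments$experiment_id),
            n_category_genes >= 3L, n_background_genes >= 1L,
            signal_sd >= 0, noise_sd > 0, background_block_size >= 1L)
  structure(list(n_category_genes = as.integer(n_category_genes),
                 n_background_genes = as.integer(n_background_genes),
                 experiments = experiments,
                 signal_sd = signal_sd, noise_sd = noise_sd,
                 background_block_size = as.integer(background_block_size),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

# Gene ids and background block assignment are a pure function of the spec
# (no RNG), so nested chains can be derived without generating values.
.synthetic_genes <- function(spec) {
  category <- sprintf("CAT%03d", seq_len(spec$n_category_genes))
  background <- sprintf("BG%03d", seq_len(spec$n_background_genes))
  block_of <- ((seq_len(spec$n_background_genes) - 1L) %/%
                 spec$background_block_size) + 1L
  list(category = category, background = background, block_of = block_of)
}

#' Generate a synthetic expression collection with planted truth
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `collection` (an `expression_collection`) and
#'   `truth` (a `synthetic_truth`: `relevant_experiments`, `partition`,
#'   and the background `block_of` assignment).
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- .synthetic_genes(spec)
  genes <- c(g$category, g$background)
  n_genes <- length(genes)
  m <- spec$n_category_genes
  exps <- spec$experiments
  set.seed(spec$rng_seed)
  blocks <- split(seq_len(spec$n_background_genes) + m, g$block_of)
  mats <- vector("list", nrow(exps))
  array_ids <- vector("list", nrow(exps))
  for (i in seq_len(nrow(exps))) {
    na <- exps$n_arrays[i]
    E <- matrix(stats::rnorm(n_genes * na, sd = spec$noise_sd),
                nrow = n_genes, ncol = na)
    if (exps$relevant[i] && spec$signal_sd > 0) {
      s <- stats::rnorm(na, sd = spec$signal_sd)
      E[seq_len(m), ] <- E[seq_len(m), ] + rep(s, each = m)
    }
    if (spec$signal_sd > 0) {
      for (rows in blocks) {
        sb <- stats::rnorm(na, sd = spec$signal_sd)
        E[rows, ] <- E[rows, ] + rep(sb, each = length(rows))
      }
    }
    mats[[i]] <- E
    array_ids[[i]] <- sprintf("%s_a%d", exps$experiment_id[i], seq_len(na))
  }
  values <- do.call(cbind, mats)
  dimnames(values) <- list(genes, unlist(array_ids))
  class(values) <- c("expression_matrix", class(values))
  map <- experiment_map(unlist(array_ids),
                        rep(exps$experiment_id, exps$n_arrays))
  collection <- expression_collection(values, map)
  truth <- structure(list(
    relevant_experiments = exps$experiment_id[exps$relevant],
    partition = gene_partition(g$category, g$background),
    block_of = stats::setNames(g$block_of, g$background)
  ), class = "synthetic_truth")
  list(collection = collection, truth = truth)
}

#' Correlation dilution curve
#'
#' Element `k + 1` is the mean absolute within-category correlation
#' computed over the arrays of the relevant experiments plus the first `k`
#' irrelevant experiments (manifest order).  With a planted signal the
#' curve decays as uninformative arrays are concatenated on; with no
#' signal it stays near the null mean `sqrt(2 / (pi * (n - 1)))`.
#'
#' @param collection An `expression_collection`.
#' @param truth A `synthetic_truth` with at least one relevant experiment.
#' @param max_noise_experiments How many irrelevant experiments to append,
#'   at most the number available.
#' @return Numeric vector of length `max_noise_experiments + 1`, named by
#'   `k`, with the profile length per step attached as attribute
#'   `"n_arrays"`.
#' @export
dilution_curve <- function(collection, truth, max_noise_experiments) {
  relevant <- truth$relevant_experiments
  stopifnot(length(relevant) >= 1L)
  irrelevant <- setdiff(experiment_ids(collection), relevant)
  if (max_noise_experiments > length(irrelevant)) {
    stop(sprintf("only %d irrelevant experiments available, %d requested",
                 length(irrelevant), max_noise_experiments))
  }
  ks <- 0:max_noise_experiments
  n_arrays <- integer(length(ks))
  out <- vapply(ks, function(k) {
    subset <- c(relevant, irrelevant[seq_len(k)])
    cm <- .cor_matrices(collection, subset, truth$partition)
    n_arrays[k + 1L] <<- cm$n_arrays
    a <- cm$A[upper.tri(cm$A)]
    mean(abs(a), na.rm = TRUE)
  }, numeric(1L))
  names(out) <- ks
  attr(out, "n_arrays") <- n_arrays
  out
}

#' Nested category chain for the specificity sweep
#'
#' Level 1 is the true planted category; each subsequent level broadens it
#' by absorbing one background co-expression block (a "sibling process"),
#' diluting the planted signal the way broader functional terms dilute
#' their most specific descendants.  The chain satisfies the nesting
#' precondition of [specificity_sweep()].
#'
#' @param spec The `synthetic_spec` the collection was generated from.
#' @param levels Number of levels (at least 2); needs `levels - 1` blocks
#'   while leaving the background non-empty.
#' @return List of `gene_partition`s ordered leaf to root.
#' @export
generate_nested_chain <- function(spec, levels) {
  stopifnot(levels >= 2L)
  g <- .synthetic_genes(spec)
  n_blocks <- max(g$block_of)
  if (levels - 1L >= n_blocks) {
    stop(sprintf("need %d background blocks for %d levels, have %d",
                 levels, levels, n_blocks))
  }
  lapply(seq_len(levels), function(lv) {
    absorbed <- g$background[g$block_of <= lv - 1L]
    gene_partition(c(g$category, absorbed), setdiff(g$background, absorbed))
  })
}

#' Write a synthetic bundle to disk
#'
#' Writes four files directly consumable by the rest of the package: the
#' expression matrix TSV, the manifest TSV, a GMT file (the category as
#' one set plus one set per background block), and a truth JSON.
#'
#' @param sim Output of [generate_collection()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_synthetic_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             gene_sets = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_expression_matrix(sim$collection$matrix, paths[["matrix"]])
  write_experiment_manifest(sim$collection$experiments, paths[["manifest"]])
  blocks <- split(names(sim$truth$block_of), sim$truth$block_of)
  sets <- c(list(category = sim$truth$partition$category),
            stats::setNames(blocks, sprintf("block%02d", as.integer(names(blocks)))))
  write_gene_sets(sets, paths[["gene_sets"]])
  writeLines(jsonlite::toJSON(list(
    relevant_experiments = sim$truth$relevant_experiments,
    category = sim$truth$partition$category,
    background = sim$truth$partition$background
  ), auto_unbox = TRUE), paths[["truth"]])
  invisible(paths)
}
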