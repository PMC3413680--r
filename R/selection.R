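# Greedy selection of relevant experiments.  The objective for a candidate
# experiment subset is the one-sided two-sample t-test p-value comparing the
# within-category correlation set A against the category-vs-background set B
# (mean(A) > mean(B)); smaller is better.  Search: rank every single
# experiment by this objective, take the K best as seeds, and grow one list
# per seed in a single randomized pass over the remaining experiments,
# keeping a candidate iff the expanded list's p-value beats the threshold L.

#' Parameters of the experiment-selection algorithm
#'
#' @param K Number of seed experiments (default 25); clamped to the number
#'   of experiments by [select_experiments()].  Selection quality is fairly
#'   insensitive to K over a wide range.
#' @param L Significance threshold in `(0, 1]` a tentatively expanded list
#'   must beat for the candidate to be kept (default 0.05); `L = 1` accepts
#'   every candidate.
#' @param ttest_variant `"pooled"` (equal-variance, the default) or
#'   `"welch"`.
#' @param use_fisher_transform If `TRUE`, apply `atanh` to all correlation
#'   values before the t-test, making them closer to Gaussian.  Off by
#'   default.
#' @param improvement_only If `TRUE`, a candidate is kept only when it both
#'   beats L and strictly improves the current list's p-value.  Off by
#'   default: the rule is the plain threshold rule.
#' @param background_sample Optional integer: subsample the background to
#'   this many genes (once per selection run) to cut computation on very
#'   large backgrounds.  `NULL` (default) uses the full background.
#' @param rng_seed Integer master seed.  Per-list substreams are derived
#'   from it by list index, so increasing K leaves earlier lists unchanged.
#' @return A `selection_params` object.
#' @export
selection_params <- function(K = 25L, L = 0.05, ttest_variant = c("pooled", "welch"),
                             use_fisher_transform = FALSE,
                             improvement_only = FALSE,
                             background_sample = NULL,
                             rng_seed = 1L) {
  ttest_variant <- match.arg(ttest_variant)
  stopifnot(K >= 1L, L > 0, L <= 1, is.numeric(rng_seed))
  structure(list(K = as.integer(K), L = L, ttest_variant = ttest_variant,
                 use_fisher_transform = isTRUE(use_fisher_transform),
                 improvement_only = isTRUE(improvement_only),
                 background_sample = background_sample,
                 rng_seed = as.integer(rng_seed)),
            class = "selection_params")
}

# One-sided two-sample t log-p on raw vectors; right tail (mean(x) > mean(y)).
.two_sample_log_p <- function(x, y, variant = "pooled") {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("need at least 2 values in each sample")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (variant == "pooled") {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (!is.finite(se) || se == 0) {
    if (mx == my) return(log(0.5))
    return(if (mx > my) -Inf else 0)
  }
  stats::pt((mx - my) / se, df = df, lower.tail = FALSE, log.p = TRUE)
}

#' Discriminatory ability of an experiment subset (log p-value)
#'
#' One-sided (right-tailed) two-sample t-test of whether the mean of the
#' within-category correlations A exceeds the mean of the
#' category-vs-background correlations B.  Computed in log space so that
#' p-values below double underflow remain comparable across subsets.
#'
#' @param sets A `correlation_sets` object.
#' @param variant `"pooled"` or `"welch"`.
#' @param use_fisher_transform Apply `atanh` to both samples first.
#' @return The natural-log p-value (\eqn{\le 0}).  Degenerate input with
#'   zero variance in both samples and equal means yields `log(0.5)`.
#' @export
discrimination_log_p <- function(sets, variant = c("pooled", "welch"),
                                 use_fisher_transform = FALSE) {
  variant <- match.arg(variant)
  a <- sets$a_values
  b <- sets$b_values
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 correlations in each of A and B")
  }
  if (use_fisher_transform) {
    cap <- 1 - 1e-12
    a <- atanh(pmin(cap, pmax(-cap, a)))
    b <- atanh(pmin(cap, pmax(-cap, b)))
  }
  .two_sample_log_p(a, b, variant)
}

# Objective for one experiment subset.
.subset_log_p <- function(collection, partition, experiment_subset, params) {
  sets <- build_correlation_sets(collection, experiment_subset, partition)
  discrimination_log_p(sets, params$ttest_variant, params$use_fisher_transform)
}

#' Rank single experiments by discriminatory ability
#'
#' Performs one t-test per experiment in the collection (each over that
#' experiment's own arrays) and returns the K best.  Ties are broken by
#' manifest order.
#'
#' @param collection An `expression_collection`.
#' @param partition A `gene_partition`.
#' @param params A `selection_params`; `params$K` rows are returned.
#' @return A data.frame with columns `experiment_id` and `log_p`, sorted by
#'   ascending `log_p`, `K` rows.
#' @export
rank_seed_experiments <- function(collection, partition, params = selection_params()) {
  ids <- experiment_ids(collection)
  if (params$K > length(ids)) {
    stop(sprintf("K = %d exceeds the number of experiments (%d)",
                 params$K, length(ids)))
  }
  lp <- vapply(ids, function(e) .subset_log_p(collection, partition, e, params),
               numeric(1L))
  ord <- order(lp, seq_along(ids))
  out <- data.frame(experiment_id = ids[ord], log_p = lp[ord],
                    stringsAsFactors = FALSE)[seq_len(params$K), ]
  rownames(out) <- NULL
  out
}

#' Grow one experiment list from a seed
#'
#' Visits every non-seed experiment once, in an order drawn from the
#' current RNG state.  Each candidate is tentatively appended; if the
#' expanded list's discrimination log-p beats `log(L)` the candidate is
#' kept, otherwise it is removed.  There is no second pass: rejected
#' experiments are never revisited.
#'
#' @param collection An `expression_collection`.
#' @param partition A `gene_partition`.
#' @param seed_experiment Experiment id the list starts from.
#' @param params A `selection_params`.
#' @param seed_log_p Optional precomputed objective of the seed alone
#'   (avoids one redundant t-test when called from [select_experiments()]).
#' @return A `list_trace`: `seed`, `visit_order`, `accepted` (includes the
#'   seed), `log_p_after_each_accept`, `final_log_p`, `n_ttests`.
#' @export
grow_list <- function(collection, partition, seed_experiment,
                      params = selection_params(), seed_log_p = NULL) {
  ids <- experiment_ids(collection)
  stopifnot(seed_experiment %in% ids)
  if (is.null(seed_log_p)) {
    seed_log_p <- .subset_log_p(collection, partition, seed_experiment, params)
  }
  candidates <- setdiff(ids, seed_experiment)
  visit_order <- if (length(candidates)) sample(candidates) else character()
  accepted <- seed_experiment
  cur_lp <- seed_log_p
  lp_trace <- numeric()
  log_L <- log(params$L)
  for (cand in visit_order) {
    lp <- .subset_log_p(collection, partition, c(accepted, cand), params)
    keep <- lp < log_L && (!params$improvement_only || lp < cur_lp)
    if (keep) {
      accepted <- c(accepted, cand)
      cur_lp <- lp
      lp_trace <- c(lp_trace, lp)
    }
  }
  structure(list(seed = seed_experiment, visit_order = visit_order,
                 accepted = accepted, log_p_after_each_accept = lp_trace,
                 final_log_p = cur_lp, n_ttests = length(visit_order)),
            class = "list_trace")
}

#' Select the experiments most relevant to a functional category
#'
#' The full seed-and-grow search: rank all experiments, grow one list per
#' seed (each list with an independent RNG substream derived from
#' `params$rng_seed`), and return the accepted set of the trace with the
#' smallest final log-p.  Ties are broken by fewer experiments, then by
#' lexicographic id order.
#'
#' @param collection An `expression_collection`.
#' @param partition A `gene_partition`.
#' @param params A `selection_params`.  `K` is clamped to the number of
#'   experiments.
#' @return A `selection_result`: `selected` (experiment ids, manifest
#'   order), `final_log_p`, `traces`, `seed_ranking`, `params`, `n_ttests`.
#' @export
select_experiments <- function(collection, partition, params = selection_params()) {
  ids <- experiment_ids(collection)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 experiments")
  params$K <- min(params$K, n)
  set.seed(params$rng_seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, params$K)
  if (!is.null(params$background_sample) &&
      params$background_sample < length(partition$background)) {
    partition$background <- sample(partition$background, params$background_sample)
  }
  all_lp <- vapply(ids, function(e) .subset_log_p(collection, partition, e, params),
                   numeric(1L))
  ord <- order(all_lp, seq_along(ids))
  ranking <- data.frame(experiment_id = ids[ord], log_p = all_lp[ord],
                        stringsAsFactors = FALSE)
  seeds <- ranking[seq_len(params$K), ]
  n_ttests <- n
  traces <- vector("list", params$K)
  for (i in seq_len(params$K)) {
    set.seed(sub_seeds[i])
    traces[[i]] <- grow_list(collection, partition, seeds$experiment_id[i],
                             params, seed_log_p = seeds$log_p[i])
    n_ttests <- n_ttests + traces[[i]]$n_ttests
  }
  final_lps <- vapply(traces, `[[`, numeric(1L), "final_log_p")
  sizes <- vapply(traces, function(tr) length(tr$accepted), integer(1L))
  keys <- vapply(traces, function(tr) paste(sort(tr$accepted), collapse = "|"),
                 character(1L))
  best <- order(final_lps, sizes, keys)[1L]
  selected <- ids[ids %in% traces[[best]]$accepted]
  structure(list(selected = selected,
                 final_log_p = final_lps[best],
                 traces = traces,
                 seed_ranking = ranking,
                 params = params,
                 n_ttests = n_ttests),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d experiment(s), final log p = %.4g (%d t-tests)\n",
              length(x$selected), x$final_log_p, x$n_ttests))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Deterministic payload (no timestamps): selected ids, final log-p,
#' parameters, per-trace decision logs and the seed ranking.
#'
#' @param result A `selection_result`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
selection_to_json <- function(result, path = NULL) {
  payload <- list(
    selected = result$selected,
    final_log_p = result$final_log_p,
    n_ttests = result$n_ttests,
    params = unclass(result$params),
    seed_ranking = result$seed_ranking,
    traces = lapply(result$traces, function(tr) {
      list(seed = tr$seed, visit_order = tr$visit_order,
           accepted = tr$accepted,
           log_p_after_each_accept = tr$log_p_after_each_accept,
           final_log_p = tr$final_log_p)
    })
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
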