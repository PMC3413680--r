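# Evaluation of an experiment subset through correlation quality:
# histogram comparison of within-category correlations, pair-classification
# ROC, guilt-by-association (GBA) function-prediction ROC, ten-fold
# cross-validation with vertically averaged ROC curves and a fold-level
# paired t-test, and the annotation-specificity sweep over nested category
# chains.

#' Area under the ROC curve from positive/negative scores
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' outscores a random negative, ties counted one half.  Equals the
#' trapezoidal area of the tie-grouped ROC curve from [roc_curve()].
#'
#' @param pos_scores,neg_scores Non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(pos_scores, neg_scores) {
  n_pos <- length(pos_scores); n_neg <- length(neg_scores)
  stopifnot(n_pos > 0L, n_neg > 0L)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve from positive/negative scores
#'
#' Scores are sorted descending; tied scores are grouped into a single
#' threshold (the curve crosses a tie block diagonally, matching the
#' half-tie convention of [auc_from_scores()]).
#'
#' @param pos_scores,neg_scores Non-empty numeric score vectors.
#' @return A `roc_curve`: list with `fpr` (ascending, starts at 0, ends at
#'   1), `tpr` aligned to it, and `auc` (trapezoidal area, equal to the
#'   Mann-Whitney AUC).
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  n_pos <- length(pos_scores); n_neg <- length(neg_scores)
  stopifnot(n_pos > 0L, n_neg > 0L)
  scores <- c(pos_scores, neg_scores)
  is_pos <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- is_pos[ord]
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_block]
  fp <- cumsum(!y)[last_of_block]
  fpr <- c(0, fp / n_neg)
  tpr <- c(0, tp / n_pos)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_curve")
}

# TPR of the ROC polyline at one FPR value.  Vertical segments (repeated
# fpr) take the topmost point at an exact hit; between two distinct fpr
# values the connecting segment runs from the top of the left block to the
# bottom of the right block.
.roc_tpr_at <- function(curve, x) {
  fpr <- curve$fpr; tpr <- curve$tpr
  hit <- fpr == x
  if (any(hit)) return(max(tpr[hit]))
  left <- max(which(fpr < x))
  right <- min(which(fpr > x))
  x1 <- fpr[left]; x2 <- fpr[right]
  y1 <- max(tpr[fpr == x1]); y2 <- min(tpr[fpr == x2])
  y1 + (y2 - y1) * (x - x1) / (x2 - x1)
}

#' Vertically average ROC curves
#'
#' Each curve's TPR is linearly interpolated on a common 101-point FPR
#' grid and averaged pointwise; at an FPR where a curve is vertical the
#' topmost point is used.
#'
#' @param curves Non-empty list of `roc_curve` objects.
#' @return A `roc_curve` on the common grid with its trapezoidal `auc`.
#' @export
average_roc <- function(curves) {
  stopifnot(length(curves) >= 1L)
  grid <- seq(0, 1, length.out = 101L)
  tprs <- vapply(curves, function(cv) {
    vapply(grid, function(x) .roc_tpr_at(cv, x), numeric(1L))
  }, numeric(101L))
  tpr <- rowMeans(tprs)
  auc <- sum(diff(grid) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = grid, tpr = tpr, auc = auc), class = "roc_curve")
}

# Zero out correlations that are not significant at alpha for profile
# length n (NULL alpha = no zeroing).  NA stays NA.
.zero_insignificant <- function(r, n_arrays, alpha) {
  if (is.null(alpha)) return(r)
  p <- correlation_pvalue(r, n_arrays)
  r[!is.na(p) & p >= alpha] <- 0
  r
}

#' Pair-classification scores for a gene partition
#'
#' Positives are within-category gene pairs, negatives are
#' category-vs-background pairs, both restricted to pairs with at least
#' one endpoint in `eval_genes` (typically a held-out test fold).  The
#' score of a pair is its Pearson correlation over the experiment subset;
#' with non-`NULL` `alpha`, correlations not significant at `alpha` are
#' zeroed, which compensates for the different profile lengths of
#' different experiment subsets.  Undefined correlations are dropped.
#'
#' @param collection An `expression_collection`.
#' @param partition A `gene_partition`.
#' @param experiments Character vector of experiment ids to correlate over.
#' @param eval_genes Gene ids the evaluation is restricted to; defaults to
#'   all genes of the partition.
#' @param alpha Significance level for zeroing, or `NULL` for raw scores.
#' @return List with numeric `pos_scores` and `neg_scores`.
#' @export
pair_scores <- function(collection, partition, experiments,
                        eval_genes = NULL, alpha = 0.05) {
  if (is.null(eval_genes)) {
    eval_genes <- c(partition$category, partition$background)
  }
  stopifnot(all(eval_genes %in% rownames(collection$matrix)))
  cm <- .cor_matrices(collection, experiments, partition)
  m <- length(partition$category)
  in_eval_cat <- partition$category %in% eval_genes
  in_eval_bg <- partition$background %in% eval_genes
  keep_a <- upper.tri(cm$A) & (outer(in_eval_cat, in_eval_cat, `|`))
  pos <- cm$A[keep_a]
  keep_b <- outer(in_eval_cat, in_eval_bg, `|`)
  neg <- cm$B[keep_b]
  pos <- pos[!is.na(pos)]
  neg <- neg[!is.na(neg)]
  if (!length(pos)) stop("no positive (within-category) pairs touch eval_genes")
  if (!length(neg)) stop("no negative (category-background) pairs touch eval_genes")
  list(pos_scores = .zero_insignificant(pos, cm$n_arrays, alpha),
       neg_scores = .zero_insignificant(neg, cm$n_arrays, alpha))
}

#' Guilt-by-association scores for candidate genes
#'
#' The simplest GBA classifier: the score of a candidate gene is the sum
#' of its correlations with the training genes of the category of
#' interest, over the given experiment subset.  Undefined correlations
#' contribute 0; with non-`NULL` `alpha`, correlations not significant at
#' `alpha` are zeroed before summing.
#'
#' @param collection An `expression_collection`.
#' @param experiments Character vector of experiment ids.
#' @param train_category Training gene ids annotated to the category.
#' @param candidates Gene ids to score; must be disjoint from
#'   `train_category`.
#' @param alpha Significance level for zeroing, or `NULL`.
#' @return Named numeric vector of scores, one per candidate.
#' @export
gba_scores <- function(collection, experiments, train_category, candidates,
                       alpha = 0.05) {
  if (!length(train_category)) stop("empty training category")
  stopifnot(!length(intersect(train_category, candidates)))
  cols <- subset_arrays(collection, experiments)
  Xt <- collection$matrix[train_category, cols, drop = FALSE]
  Xc <- collection$matrix[candidates, cols, drop = FALSE]
  if (!anyNA(Xt) && !anyNA(Xc)) {
    R <- tcrossprod(.std_rows(Xc), .std_rows(Xt))
  } else {
    R <- suppressWarnings(stats::cor(t(Xc), t(Xt), use = "pairwise.complete.obs"))
    R[tcrossprod(!is.na(Xc) * 1, !is.na(Xt) * 1) < 3] <- NA_real_
  }
  R[!is.na(R)] <- pmin(1, pmax(-1, R[!is.na(R)]))
  R <- .zero_insignificant(R, length(cols), alpha)
  R[is.na(R)] <- 0
  stats::setNames(rowSums(R), candidates)
}

# Paired one-sided t-test that (1-AUC) under "all" exceeds (1-AUC) under
# "selected".  Degenerate all-equal folds give 0.5.
.fold_ttest_p <- function(one_minus_all, one_minus_sel) {
  d <- one_minus_all - one_minus_sel
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(0.5)
    return(if (mean(d) > 0) 0 else 1)
  }
  stats::t.test(one_minus_all, one_minus_sel, paired = TRUE,
                alternative = "greater")$p.value
}

#' Cross-validated comparison of selected vs all experiments
#'
#' Genes are split into `folds` stratified folds (category genes spread
#' evenly across folds, background genes likewise).  In each round the
#' selection algorithm runs on the training genes only, and both the
#' selected subset and the full collection are evaluated on the held-out
#' genes:
#' * `mode = "pair"`: pair classification via [pair_scores()] with
#'   `eval_genes` = the test fold (pairs with at least one test-fold
#'   endpoint);
#' * `mode = "gba"`: gene function prediction via [gba_scores()] with the
#'   training category genes as the training set and the test genes as
#'   candidates.
#'
#' @param collection An `expression_collection`.
#' @param partition A `gene_partition` with at least `folds` category
#'   genes.
#' @param mode `"pair"` or `"gba"`.
#' @param params A `selection_params`; `params$rng_seed` also seeds the
#'   fold assignment, so a fixed seed gives a bit-reproducible report.
#' @param folds Number of folds, default 10.
#' @param alpha Significance level for score zeroing (default 0.05), or
#'   `NULL` for raw correlations.
#' @return A `cv_report`: per-fold AUCs for the selected and the full
#'   subset, their mean (1-AUC), vertically averaged ROC curves, the
#'   paired one-sided fold t-test p-value, the per-fold selections and the
#'   fold assignment.
#' @export
cross_validate <- function(collection, partition, mode = c("pair", "gba"),
                           params = selection_params(), folds = 10L,
                           alpha = 0.05) {
  mode <- match.arg(mode)
  m <- length(partition$category)
  if (m < folds) {
    stop(sprintf("category has %d genes; need at least one per fold (%d folds)",
                 m, folds))
  }
  set.seed(params$rng_seed)
  fold_of_cat <- stats::setNames(
    sample(rep_len(seq_len(folds), m)), sample(partition$category))
  fold_of_bg <- stats::setNames(
    sample(rep_len(seq_len(folds), length(partition$background))),
    sample(partition$background))
  fold_seeds <- sample.int(.Machine$integer.max - 1L, folds)
  all_ids <- experiment_ids(collection)

  auc_sel <- auc_all <- numeric(folds)
  curves_sel <- curves_all <- vector("list", folds)
  selections <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_cat <- names(fold_of_cat)[fold_of_cat == f]
    test_bg <- names(fold_of_bg)[fold_of_bg == f]
    train_part <- gene_partition(setdiff(partition$category, test_cat),
                                 setdiff(partition$background, test_bg))
    fp <- params
    fp$rng_seed <- fold_seeds[f]
    sel <- select_experiments(collection, train_part, fp)
    selections[[f]] <- sel
    eval_one <- function(exps) {
      if (mode == "pair") {
        sc <- pair_scores(collection, partition, exps,
                          eval_genes = c(test_cat, test_bg), alpha = alpha)
        list(pos = sc$pos_scores, neg = sc$neg_scores)
      } else {
        sc <- gba_scores(collection, exps,
                         train_category = train_part$category,
                         candidates = c(test_cat, test_bg), alpha = alpha)
        list(pos = sc[test_cat], neg = sc[test_bg])
      }
    }
    for (which in c("sel", "all")) {
      sc <- eval_one(if (which == "sel") sel$selected else all_ids)
      cv <- roc_curve(sc$pos, sc$neg)
      if (which == "sel") {
        auc_sel[f] <- cv$auc; curves_sel[[f]] <- cv
      } else {
        auc_all[f] <- cv$auc; curves_all[[f]] <- cv
      }
    }
  }
  structure(list(
    mode = mode,
    folds = folds,
    fold_auc_selected = auc_sel,
    fold_auc_all = auc_all,
    mean_one_minus_auc_selected = 1 - mean(auc_sel),
    mean_one_minus_auc_all = 1 - mean(auc_all),
    avg_roc_selected = average_roc(curves_sel),
    avg_roc_all = average_roc(curves_all),
    fold_ttest_p = .fold_ttest_p(1 - auc_all, 1 - auc_sel),
    selections = selections,
    fold_of_category = fold_of_cat,
    fold_of_background = fold_of_bg,
    eval_convention = "pairs/candidates with >= 1 endpoint in the test fold",
    params = params,
    alpha = alpha
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%s mode, %d folds)\n", x$mode, x$folds))
  cat(sprintf("  mean(1-AUC) selected: %.4f   all: %.4f   fold t-test p = %.3g\n",
              x$mean_one_minus_auc_selected, x$mean_one_minus_auc_all,
              x$fold_ttest_p))
  invisible(x)
}

#' Compare within-category correlation distributions: selected vs all
#'
#' Computes within-category correlations over the selected subset and over
#' all experiments, keeps only those significant at `alpha` (each subset
#' filtered at its own profile length), bins both on `[-1, 1]`, and tests
#' one-sidedly whether the absolute correlations of the selected subset
#' exceed those of the full collection.
#'
#' @param collection An `expression_collection`.
#' @param partition A `gene_partition`.
#' @param selected Non-empty character vector of experiment ids.
#' @param alpha Significance filter level, default 0.05.
#' @param bins Number of histogram bins over `[-1, 1]`, default 40.
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @return List with `breaks`, `counts_selected`, `counts_all`,
#'   `log_p` (natural-log one-sided p, selected > all on `|r|`), and the
#'   retained/dropped counts for both subsets.
#' @export
compare_histograms <- function(collection, partition, selected,
                               alpha = 0.05, bins = 40L,
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(selected) >= 1L)
  sets_sel <- build_correlation_sets(collection, selected, partition)
  sets_all <- build_correlation_sets(collection, experiment_ids(collection),
                                     partition)
  r_sel <- filter_significant(sets_sel$a_values, sets_sel$n_arrays, alpha)
  r_all <- filter_significant(sets_all$a_values, sets_all$n_arrays, alpha)
  if (!length(r_sel) || !length(r_all)) {
    stop(sprintf(paste0("no significant within-category correlations ",
                        "(selected: %d of %d retained; all: %d of %d)"),
                 length(r_sel), length(sets_sel$a_values),
                 length(r_all), length(sets_all$a_values)))
  }
  breaks <- seq(-1, 1, length.out = bins + 1L)
  identical_sets <- setequal(selected, experiment_ids(collection))
  log_p <- if (identical_sets) log(0.5) else {
    .two_sample_log_p(abs(r_sel), abs(r_all), variant)
  }
  list(breaks = breaks,
       counts_selected = graphics::hist(r_sel, breaks = breaks, plot = FALSE)$counts,
       counts_all = graphics::hist(r_all, breaks = breaks, plot = FALSE)$counts,
       values_selected = r_sel,
       values_all = r_all,
       n_retained_selected = length(r_sel),
       n_retained_all = length(r_all),
       dropped_selected = sets_sel$dropped_pairs,
       dropped_all = sets_all$dropped_pairs,
       log_p = log_p)
}

#' Annotation-specificity sweep over a nested category chain
#'
#' Runs the pair-mode cross-validation at every level of a leaf-to-root
#' chain of nested partitions and returns, per level, the improvement of
#' the selected subset over the full collection:
#' `mean(1-AUC)_all - mean(1-AUC)_selected`.  Larger is better; the
#' improvement is expected to shrink as the category broadens.
#'
#' @param collection An `expression_collection`.
#' @param nested_partitions List of `gene_partition`s ordered leaf to
#'   root; each category must contain the previous one.
#' @param params A `selection_params`.
#' @param folds Number of CV folds, default 10.
#' @param alpha Significance level for score zeroing.
#' @return Numeric vector of (1-AUC) differences, one per level, with the
#'   per-level `cv_report`s attached as attribute `"reports"`.
#' @export
specificity_sweep <- function(collection, nested_partitions,
                              params = selection_params(), folds = 10L,
                              alpha = 0.05) {
  stopifnot(length(nested_partitions) >= 1L)
  for (i in seq_along(nested_partitions)[-1L]) {
    if (!all(nested_partitions[[i - 1L]]$category %in%
             nested_partitions[[i]]$category)) {
      stop("partition chain is not nested at level ", i)
    }
  }
  reports <- lapply(nested_partitions, function(p) {
    cross_validate(collection, p, mode = "pair", params = params,
                   folds = folds, alpha = alpha)
  })
  diffs <- vapply(reports, function(r) {
    r$mean_one_minus_auc_all - r$mean_one_minus_auc_selected
  }, numeric(1L))
  attr(diffs, "reports") <- reports
  diffs
}

#' Serialize a cross-validation report to JSON
#'
#' Deterministic payload: mode, per-fold AUCs, means, averaged curves,
#' fold t-test p, per-fold selected experiment ids, and the evaluation
#' convention used for test pairs.
#'
#' @param report A `cv_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
cv_report_to_json <- function(report, path = NULL) {
  payload <- list(
    mode = report$mode,
    folds = report$folds,
    fold_auc_selected = report$fold_auc_selected,
    fold_auc_all = report$fold_auc_all,
    mean_one_minus_auc_selected = report$mean_one_minus_auc_selected,
    mean_one_minus_auc_all = report$mean_one_minus_auc_all,
    fold_ttest_p = report$fold_ttest_p,
    avg_roc_selected = report$avg_roc_selected[c("fpr", "tpr", "auc")],
    avg_roc_all = report$avg_roc_all[c("fpr", "tpr", "auc")],
    selected_per_fold = lapply(report$selections, `[[`, "selected"),
    eval_convention = report$eval_convention,
    alpha = report$alpha,
    params = unclass(report$params)
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
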