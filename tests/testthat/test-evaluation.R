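# ROC machinery, pair/GBA scoring, cross-validation and the specificity
# sweep.

# Independent oracle: exhaustive enumeration of positive/negative pairs.
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

test_that("AUC matches the exhaustive pair-enumeration oracle", {
  expect_equal(auc_from_scores(c(3, 4), c(1, 2)), 1)
  expect_equal(auc_from_scores(c(1, 1, 1), c(1, 1, 1)), 0.5)
  expect_equal(auc_from_scores(c(1, 3), c(2, 4)), 0.25)
  set.seed(21)
  for (rep in 1:50) {
    pos <- sample(1:8, sample(1:25, 1), replace = TRUE) # many ties
    neg <- sample(1:8, sample(1:25, 1), replace = TRUE)
    expect_equal(auc_from_scores(pos, neg), auc_oracle(pos, neg))
    expect_equal(auc_from_scores(-pos, -neg), 1 - auc_oracle(pos, neg))
  }
})

test_that("ROC curves are monotone, trapezoid-consistent and AUC-consistent", {
  set.seed(22)
  for (rep in 1:20) {
    pos <- rnorm(sample(3:30, 1), 0.5)
    neg <- rnorm(sample(3:30, 1))
    cv <- roc_curve(pos, neg)
    expect_true(all(diff(cv$tpr) >= 0))
    expect_true(all(diff(cv$fpr) >= 0))
    expect_equal(range(cv$fpr), c(0, 1))
    trap <- sum(diff(cv$fpr) * (cv$tpr[-1] + cv$tpr[-length(cv$tpr)]) / 2)
    expect_equal(cv$auc, trap, tolerance = 1e-9)
    expect_equal(cv$auc, auc_from_scores(pos, neg), tolerance = 1e-12)
  }
})

test_that("vertical ROC averaging interpolates on a common grid", {
  diag_curve <- roc_curve(c(1, 3), c(2, 4))   # imperfect
  same <- average_roc(list(diag_curve, diag_curve))
  # equality up to the grid resolution (step corners sampled at 0.01)
  expect_lt(abs(same$auc - diag_curve$auc), 0.01)
  # away from the step corners the polyline is reproduced exactly
  expect_equal(same$tpr[same$fpr == 0.25], 0)
  expect_equal(same$tpr[same$fpr == 0.75], 0.5)
  # y = x versus the perfect classifier: midpoint at fpr 0.5 is 0.75
  chance <- structure(list(fpr = c(0, 1), tpr = c(0, 1), auc = 0.5),
                      class = "roc_curve")
  perfect <- roc_curve(c(2, 3), c(0, 1))
  avg <- average_roc(list(chance, perfect))
  expect_equal(avg$tpr[avg$fpr == 0.5], 0.75)
  expect_true(avg$auc >= 0.5 && avg$auc <= 1)
})

test_that("pair scores enumerate the expected pairs", {
  sim <- small_planted(33, n_category = 5L, n_background = 10L,
                       n_relevant = 2L, n_irrelevant = 2L)
  part <- sim$truth$partition
  sc <- pair_scores(sim$collection, part, experiment_ids(sim$collection),
                    alpha = NULL)
  expect_length(sc$pos_scores, 5 * 4 / 2)
  expect_length(sc$neg_scores, 5 * 10)
  expect_error(pair_scores(sim$collection, part,
                           experiment_ids(sim$collection),
                           eval_genes = part$background[1:3]),
               "no positive")
})

test_that("pair classification on relevant experiments separates planted categories", {
  sim <- small_planted(34)
  sc <- pair_scores(sim$collection, sim$truth$partition,
                    sim$truth$relevant_experiments)
  expect_gt(auc_from_scores(sc$pos_scores, sc$neg_scores), 0.9)
})

test_that("GBA scores sum correlations to the training set", {
  cc <- tiny_collection()
  sc <- gba_scores(cc, experiment_ids(cc),
                   train_category = c("CAT1", "CAT2", "CAT3"),
                   candidates = c("BG1", "BG2"), alpha = NULL)
  manual <- vapply(c("BG1", "BG2"), function(g) {
    sum(vapply(c("CAT1", "CAT2", "CAT3"), function(t) {
      pearson(cc$matrix[g, ], cc$matrix[t, ])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(sc, manual, tolerance = 1e-12)
  # a candidate identical in profile to a training gene contributes 1.0
  cc$matrix["BG1", ] <- cc$matrix["CAT1", ]
  sc1 <- gba_scores(cc, experiment_ids(cc), c("CAT1", "CAT2", "CAT3"),
                    "BG1", alpha = NULL)
  r23 <- pearson(cc$matrix["CAT1", ], cc$matrix["CAT2", ]) +
    pearson(cc$matrix["CAT1", ], cc$matrix["CAT3", ])
  expect_equal(unname(sc1), 1 + r23, tolerance = 1e-12)
  expect_error(gba_scores(cc, experiment_ids(cc), character(), "BG1"),
               "empty training")
})

test_that("held-out planted category genes outscore background under GBA", {
  sim <- small_planted(35)
  part <- sim$truth$partition
  held_cat <- part$category[1:5]
  sc <- gba_scores(sim$collection, sim$truth$relevant_experiments,
                   train_category = setdiff(part$category, held_cat),
                   candidates = c(held_cat, part$background))
  expect_gt(mean(sc[held_cat]), mean(sc[part$background]))
})

test_that("cross-validation with selection forced to the full set is a wash", {
  sim <- small_planted(36, n_category = 12L, n_background = 30L,
                       n_relevant = 2L, n_irrelevant = 2L)
  # L = 1 accepts every candidate, so selected == all in every fold
  report <- cross_validate(sim$collection, sim$truth$partition, "pair",
                           selection_params(K = 2L, L = 1, rng_seed = 8L),
                           folds = 10L)
  expect_equal(report$fold_auc_selected, report$fold_auc_all)
  expect_equal(report$mean_one_minus_auc_selected,
               report$mean_one_minus_auc_all)
  expect_gte(report$fold_ttest_p, 0.5)
  expect_equal(report$mean_one_minus_auc_selected,
               1 - mean(report$fold_auc_selected), tolerance = 1e-12)
})

test_that("cross-validation reports are bit-reproducible and stratified", {
  sim <- small_planted(37, n_category = 12L, n_background = 30L,
                       n_relevant = 2L, n_irrelevant = 3L)
  params <- selection_params(K = 3L, rng_seed = 99L)
  r1 <- cross_validate(sim$collection, sim$truth$partition, "gba", params,
                       folds = 10L)
  r2 <- cross_validate(sim$collection, sim$truth$partition, "gba", params,
                       folds = 10L)
  expect_identical(cv_report_to_json(r1), cv_report_to_json(r2))
  # stratification: every fold holds at least one category gene
  expect_identical(sort(unique(unname(r1$fold_of_category))), 1:10)
  expect_length(r1$fold_auc_selected, 10L)
  # leave-one-category-gene-out boundary
  r3 <- cross_validate(sim$collection, sim$truth$partition, "pair",
                       selection_params(K = 2L, rng_seed = 5L), folds = 12L)
  expect_length(r3$fold_auc_selected, 12L)
})

test_that("label shuffling calibrates pair AUC to chance", {
  sim <- small_planted(38, n_category = 10L, n_background = 30L,
                       n_relevant = 2L, n_irrelevant = 2L)
  cc <- sim$collection
  genes <- c(sim$truth$partition$category, sim$truth$partition$background)
  set.seed(40)
  aucs <- vapply(1:50, function(i) {
    shuffled <- sample(genes)
    part <- gene_partition(shuffled[1:10], shuffled[-(1:10)])
    sc <- pair_scores(cc, part, experiment_ids(cc), alpha = NULL)
    auc_from_scores(sc$pos_scores, sc$neg_scores)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("histogram comparison detects the planted enrichment", {
  sim <- small_planted(39)
  hc <- compare_histograms(sim$collection, sim$truth$partition,
                           sim$truth$relevant_experiments, bins = 40L)
  expect_length(hc$counts_selected, 40L)
  expect_identical(sum(hc$counts_selected), hc$n_retained_selected)
  expect_identical(sum(hc$counts_all), hc$n_retained_all)
  frac_high <- function(v) mean(abs(v) > 0.5)
  expect_gt(frac_high(hc$values_selected), frac_high(hc$values_all))
  expect_lt(hc$log_p, log(0.05))
  # identity: comparing the full collection against itself is a coin flip
  hc_id <- compare_histograms(sim$collection, sim$truth$partition,
                              experiment_ids(sim$collection))
  expect_equal(hc_id$log_p, log(0.5))
})

test_that("specificity sweep composes cross-validation and checks nesting", {
  sp <- synthetic_spec(n_category_genes = 10L, n_background_genes = 30L,
                       n_relevant = 2L, n_irrelevant = 2L,
                       background_block_size = 10L, rng_seed = 41L)
  sim <- generate_collection(sp)
  part <- sim$truth$partition
  params <- selection_params(K = 2L, rng_seed = 17L)
  d1 <- specificity_sweep(sim$collection, list(part), params, folds = 5L)
  rep1 <- attr(d1, "reports")[[1]]
  expect_equal(as.numeric(d1),
               rep1$mean_one_minus_auc_all - rep1$mean_one_minus_auc_selected)
  broken <- list(gene_partition(part$category[-1], part$background),
                 gene_partition(part$category[2:4],
                                part$background))
  expect_error(specificity_sweep(sim$collection, broken, params, folds = 3L),
               "not nested")
})
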