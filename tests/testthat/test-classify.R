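# Synthetic separable table: feature `sep` encodes the class with a margin,
# the remaining features are noise.
separable_table <- function(n = 64, classes = c("A", "B"), n_noise = 4,
                            seed = 1, schema_groups = FALSE) {
  set.seed(seed)
  y <- rep(classes, length.out = n)
  sep <- as.integer(factor(y)) * 3 + rnorm(n, 0, 0.3)
  tab <- data.frame(row_id = paste0("c", 1:n, "::s"), case_id = paste0("c", 1:n),
                    session_id = "s", class_label = y, sep = sep,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_noise)) tab[[paste0("noise", k)]] <- rnorm(n)
  tab <- structure(tab, class = c("feature_table", "data.frame"))
  if (schema_groups) {
    attr(tab, "schema") <- data.frame(
      column = c("sep", paste0("noise", seq_len(n_noise))),
      structure = "x", feature = "x", aggregate = "mean", units = "",
      group = c("cardiac", rep("glcm", n_noise)), stringsAsFactors = FALSE)
  }
  tab
}

test_that("all five classifier families fit, predict and reject bad configs", {
  tab <- separable_table(n = 40, seed = 2)
  for (cfg in default_grid()) {
    m <- fit_final(tab, cfg, seed = 5)
    pred <- predict(m, tab)
    expect_gte(mean(pred == tab$class_label), 0.9)
    pr <- predict(m, tab, type = "prob")
    expect_equal(dim(pr), c(40, 2))
    expect_equal(unname(rowSums(pr)), rep(1, 40), tolerance = 1e-6)
  }
  # the tuned random-forest configuration (230 trees, depth 6, leaf 6)
  rf <- list(family = "random_forest",
             hyperparameters = list(num.trees = 230, max.depth = 6,
                                    min.node.size = 6))
  expect_s3_class(fit_final(tab, rf, seed = 1), "cmr_model")
  # the tuned extra-trees configuration (190 trees)
  et <- list(family = "extra_trees", hyperparameters = list(num.trees = 190))
  expect_s3_class(fit_final(tab, et, seed = 1), "cmr_model")
  # out-of-grid values rejected
  expect_error(fit_final(tab, list(family = "random_forest",
                                   hyperparameters = list(max.depth = -1))),
               "out of grid")
  expect_error(fit_final(tab, list(family = "no_such_family")), "unknown")
})

test_that("evaluate computes standard metrics and rank-statistic AUC", {
  # perfect 5-class prediction
  tab5 <- separable_table(n = 20, classes = c("a", "b", "c", "d", "e"),
                          seed = 3)
  m <- fit_final(tab5, default_grid()[[5]], seed = 1)
  ev <- evaluate(m, tab5)
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(ev$precision), rep(1, 5))
  expect_equal(unname(ev$recall), rep(1, 5))
  expect_equal(ev$macro_auc, 1)
  # confusion arithmetic: [[3,1],[1,3]]
  cm <- cardioloop:::classification_metrics(
    truth = rep(c("x", "y"), each = 4),
    pred = c("x", "x", "x", "y", "y", "y", "y", "x"),
    probs = matrix(0.5, 8, 2, dimnames = list(NULL, c("x", "y"))),
    classes = c("x", "y"))
  expect_equal(cm$accuracy, 0.75)
  expect_equal(unname(cm$recall), c(0.75, 0.75))
  # AUC equals the Mann-Whitney pair-counting oracle, ties included
  set.seed(8)
  for (i in 1:10) {
    scores <- sample(seq(0, 1, 0.1), 6, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    if (all(pos) || !any(pos)) next
    expect_equal(cardioloop:::auc_rank(scores, pos), oracle_auc(scores, pos))
  }
  # and the pROC cross-check on a larger score set
  set.seed(9)
  sc <- rnorm(40); lab <- rep(c(TRUE, FALSE), 20)
  expect_equal(cardioloop:::auc_rank(sc, lab),
               as.numeric(suppressMessages(pROC::auc(pROC::roc(lab, sc,
                                                               quiet = TRUE)))),
               tolerance = 1e-12)
})

test_that("nested CV separates separable data and stays at chance for noise", {
  tab <- separable_table(n = 64, seed = 4, schema_groups = TRUE)
  res <- nested_cv(tab, outer_folds = 8, inner_folds = 4, seed = 7)
  expect_gte(res$accuracy, 0.95)
  expect_equal(sum(res$confusion), 64)
  expect_equal(res$accuracy, sum(diag(res$confusion)) / sum(res$confusion))
  expect_equal(res$macro_auc, mean(res$auc))
  # determinism: identical seed, identical result
  res2 <- nested_cv(tab, outer_folds = 8, inner_folds = 4, seed = 7)
  expect_identical(res$fold_scores, res2$fold_scores)
  expect_identical(res$confusion, res2$confusion)
  expect_identical(res$selected, res2$selected)

  # permuted labels: chance-level accuracy for a balanced 2-class problem
  set.seed(11)
  tabp <- tab
  tabp$class_label <- sample(tabp$class_label)
  resp <- nested_cv(tabp, grid = default_grid()[c(1, 5)], outer_folds = 4,
                    inner_folds = 3, seed = 7)
  expect_gte(resp$accuracy, 0.3 - 1e-9)
  expect_lte(resp$accuracy, 0.7 + 1e-9)

  # single-class tables are rejected
  tab1 <- tab; tab1$class_label <- "A"
  expect_error(nested_cv(tab1), "two classes")
  # too-small classes reduce the folds with a warning
  tab_small <- separable_table(n = 10, seed = 5)
  w <- capture_warnings(nested_cv(tab_small, grid = default_grid()[5],
                                  outer_folds = 8, inner_folds = 8, seed = 1))
  expect_true(any(grepl("folds reduced", w)))
})

test_that("no leakage: preprocessing is fitted on training folds only", {
  tab <- separable_table(n = 32, seed = 6)
  tr <- tab[1:24, ]; te <- tab[25:32, ]
  m <- fit_final(tr, default_grid()[[1]], seed = 3)
  # shuffling test labels cannot change the fitted preprocessing
  te2 <- te; te2$class_label <- rev(te2$class_label)
  expect_identical(m$preproc, fit_final(tr, default_grid()[[1]], seed = 3)$preproc)
  expect_identical(predict(m, te), predict(m, te2))
  # the preprocessing statistics equal the training-column statistics
  expect_equal(unname(m$preproc$mean["sep"]), mean(tr$sep))
})

test_that("permutation importance isolates the informative feature", {
  tab <- separable_table(n = 60, seed = 12)
  tab$constant <- 5
  m <- fit_final(tab, default_grid()[[5]], seed = 2)
  imp <- permutation_importance(m, tab, repeats = 5, seed = 3)
  expect_equal(imp$importance[imp$feature == "constant"], 0)
  expect_equal(imp$feature[1], "sep")
  others <- imp$importance[!imp$feature %in% c("sep")]
  expect_true(all(abs(others) < imp$importance[1] / 2))
  # more repeats keep the sign of the top importance and shrink the Monte
  # Carlo standard error of its mean (sd / sqrt(repeats))
  imp1 <- permutation_importance(m, tab, repeats = 5, seed = 3)
  imp2 <- permutation_importance(m, tab, repeats = 30, seed = 3)
  expect_gt(imp1$importance[imp1$feature == "sep"], 0)
  expect_gt(imp2$importance[imp2$feature == "sep"], 0)
  expect_lte(imp2$sd[imp2$feature == "sep"] / sqrt(30),
             imp1$sd[imp1$feature == "sep"] / sqrt(5) + 1e-9)
  # a duplicated informative feature splits importance
  tabd <- tab; tabd$sep2 <- tabd$sep
  md <- fit_final(tabd, default_grid()[[5]], seed = 2)
  impd <- permutation_importance(md, tabd, repeats = 5, seed = 3)
  solo <- imp$importance[imp$feature == "sep"]
  expect_lte(impd$importance[impd$feature == "sep"], solo + 1e-9)
  expect_lte(impd$importance[impd$feature == "sep2"], solo + 1e-9)
})

test_that("the improvement loop is a no-op at zero corruption", {
  gen <- generate_cohort(tiny_phantom_config(n_cases = 12, seed = 71,
                                             class_mix = c(NOR = 0.5, HCM = 0.5)))
  res <- improvement_loop(gen$cohort, gen$truth, corruption_rate = 0, seed = 5,
                          grid = default_grid()[5], outer_folds = 3,
                          inner_folds = 2)
  expect_equal(res$accuracy_after, res$accuracy_before)
  expect_length(res$corrected_cases, 0)
  expect_true(all(res$corrected_cases %in% res$worklist$case_id))
})
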