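# Multi-modal disease classification: nested cross-validated model selection
# over five classifier families, final evaluation, permutation feature
# importance, and the expert-in-the-loop improvement loop.
#
# The inner CV selects (classifier family x hyperparameters x feature-class
# subset) by mean inner accuracy; imputation and standardization are fitted
# on training folds only.  Candidate grids are deliberately small and
# config-overridable; ties are broken towards the earlier candidate in the
# grid, which is ordered from simpler to more complex models.

#' Default model-selection grid
#'
#' One representative configuration per family, ordered simple to complex:
#' logistic regression, RBF-SVM, gradient boosting, extra-trees and random
#' forest.  The tree ensembles use the hyperparameters reported for the
#' tuned cardiac classifiers (random forest: 230 trees, Gini, depth 6,
#' minimum leaf 6; extra-trees: 190 trees); `min_samples_split` has no ranger
#' equivalent and is represented by the leaf-size constraint.
#'
#' @return List of model configs (`family`, `hyperparameters`).
#' @export
default_grid <- function() {
  list(
    list(family = "logistic", hyperparameters = list(decay = 0.01)),
    list(family = "svm_rbf", hyperparameters = list(cost = 1)),
    list(family = "gradient_boosting",
         hyperparameters = list(nrounds = 60, max_depth = 3, eta = 0.3)),
    list(family = "extra_trees",
         hyperparameters = list(num.trees = 190, max.depth = 6, min.node.size = 6)),
    list(family = "random_forest",
         hyperparameters = list(num.trees = 230, max.depth = 6, min.node.size = 6)))
}

model_families <- c("random_forest", "extra_trees", "gradient_boosting",
                    "svm_rbf", "logistic")

validate_model_config <- function(config) {
  if (!is.list(config) || is.null(config$family)) stop2("model config needs a 'family'")
  if (!config$family %in% model_families) {
    stop2("unknown classifier family '%s'", config$family)
  }
  h <- config$hyperparameters %||% list()
  chk <- function(name, lo) {
    if (!is.null(h[[name]]) && (!is.numeric(h[[name]]) || h[[name]] < lo)) {
      stop2("hyperparameter '%s' = %s out of grid domain (>= %s)",
            name, h[[name]], lo)
    }
  }
  chk("num.trees", 1); chk("max.depth", 0); chk("min.node.size", 1)
  chk("nrounds", 1); chk("max_depth", 1); chk("eta", 1e-6)
  chk("cost", 1e-6); chk("gamma", 1e-9); chk("decay", 0)
  invisible(config)
}

fit_preproc <- function(X) {
  med <- vapply(X, function(x) median(x, na.rm = TRUE), 0)
  med[!is.finite(med)] <- 0
  Xi <- as.data.frame(mapply(function(x, m) ifelse(is.na(x), m, x), X, med,
                             SIMPLIFY = FALSE))
  mu <- vapply(Xi, mean, 0)
  sdev <- vapply(Xi, sd, 0)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(median = med, mean = mu, sd = sdev, columns = names(X))
}

apply_preproc <- function(preproc, X) {
  X <- X[, preproc$columns, drop = FALSE]
  for (j in seq_along(preproc$columns)) {
    x <- X[[j]]
    x[is.na(x)] <- preproc$median[j]
    X[[j]] <- (x - preproc$mean[j]) / preproc$sd[j]
  }
  X
}

#' Fit one classifier configuration
#'
#' Fits median imputation + standardization (training data only) and the
#' configured classifier.  The handle predicts class probabilities for all
#' five families (decision values are min-max rescaled to scores where no
#' native probability exists).
#'
#' @param table A `feature_table` with a `class_label` column.
#' @param config Model config (see [default_grid()]).
#' @param seed Integer seed (all stochastic families are seeded).
#' @param features Feature columns to use (default: all).
#' @return Object of class `cmr_model` supporting [predict()] (class labels)
#'   and `predict(type = "prob")`.
#' @export
fit_final <- function(table, config, seed = 1L, features = NULL) {
  validate_model_config(config)
  features <- features %||% feature_columns(table)
  y <- factor(table$class_label)
  if (nlevels(y) < 2) stop2("need at least two classes to fit a classifier")
  X <- as.data.frame(table)[, features, drop = FALSE]
  preproc <- fit_preproc(X)
  Xs <- apply_preproc(preproc, X)
  h <- config$hyperparameters %||% list()
  set.seed(seed)
  fit <- switch(config$family,
    random_forest = ranger::ranger(
      x = Xs, y = y, probability = TRUE, num.threads = 1, seed = seed,
      num.trees = h$num.trees %||% 230, max.depth = h$max.depth %||% 6,
      min.node.size = h$min.node.size %||% 6),
    extra_trees = ranger::ranger(
      x = Xs, y = y, probability = TRUE, num.threads = 1, seed = seed,
      splitrule = "extratrees", num.random.splits = 1, replace = FALSE,
      sample.fraction = 1,
      num.trees = h$num.trees %||% 190, max.depth = h$max.depth %||% 6,
      min.node.size = h$min.node.size %||% 6),
    gradient_boosting = {
      params <- list(max_depth = h$max_depth %||% 3, eta = h$eta %||% 0.3,
                     nthread = 1, seed = seed)
      if (nlevels(y) > 2) {
        params$objective <- "multi:softprob"; params$num_class <- nlevels(y)
      } else {
        params$objective <- "binary:logistic"
      }
      dm <- xgboost::xgb.DMatrix(as.matrix(Xs), label = as.integer(y) - 1,
                                 nthread = 1)
      xgboost::xgb.train(params = params, data = dm,
                         nrounds = h$nrounds %||% 60, verbose = 0)
    },
    svm_rbf = e1071::svm(
      x = as.matrix(Xs), y = y, kernel = "radial", probability = TRUE,
      scale = FALSE,  # inputs already standardized by the preproc step
      cost = h$cost %||% 1, gamma = h$gamma %||% (1 / ncol(Xs))),
    logistic = {
      dat <- cbind(.y = y, Xs)
      nnet::multinom(.y ~ ., data = dat, decay = h$decay %||% 0.01,
                     trace = FALSE, maxit = 300,
                     MaxNWts = 2000 + nlevels(y) * ncol(Xs) * 2)
    })
  base::structure(list(config = config, preproc = preproc, fit = fit,
                       classes = levels(y), features = features, seed = seed),
                  class = "cmr_model")
}

#' @export
predict.cmr_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.data.frame(newdata)[, object$features, drop = FALSE]
  Xs <- apply_preproc(object$preproc, X)
  K <- length(object$classes)
  probs <- switch(object$config$family,
    random_forest = , extra_trees = {
      p <- predict(object$fit, data = Xs, num.threads = 1)$predictions
      p[, object$classes, drop = FALSE]
    },
    gradient_boosting = {
      p <- predict(object$fit, xgboost::xgb.DMatrix(as.matrix(Xs), nthread = 1))
      if (K > 2) {
        if (is.null(dim(p))) p <- matrix(p, ncol = K, byrow = TRUE)
        colnames(p) <- object$classes
        p
      } else {
        m <- cbind(1 - p, p)
        colnames(m) <- object$classes
        m
      }
    },
    svm_rbf = {
      pr <- predict(object$fit, as.matrix(Xs), probability = TRUE)
      attr(pr, "probabilities")[, object$classes, drop = FALSE]
    },
    logistic = {
      p <- predict(object$fit, newdata = Xs, type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p)
      colnames(p) <- object$classes
      p
    })
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

stratified_folds <- function(y, k, seed) {
  min_class <- min(table(y))
  if (min_class < k) {
    k <- max(2L, min_class)
    warning(sprintf("too few cases per class; folds reduced to %d", k))
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))[sample(length(idx))]
  }
  list(fold = fold, k = k)
}

accuracy_score <- function(truth, pred) mean(as.character(truth) == as.character(pred))

# Rank-based ROC AUC (equals the Mann-Whitney U statistic / (n1 * n2)).
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

classification_metrics <- function(truth, pred, probs, classes) {
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  cm <- table(truth = truth, pred = pred)
  acc <- sum(diag(cm)) / sum(cm)
  precision <- diag(cm) / pmax(colSums(cm), 1)
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  auc <- vapply(classes, function(cl) {
    auc_rank(probs[, cl], truth == cl)
  }, 0)
  list(accuracy = acc, confusion = cm, precision = precision, recall = recall,
       auc = auc, macro_auc = mean(auc, na.rm = TRUE))
}

#' Evaluate a fitted model on a test table
#'
#' @param model A `cmr_model`.
#' @param test_table A `feature_table` with `class_label`.
#' @return List with `accuracy`, `confusion`, per-class `precision` /
#'   `recall`, one-vs-rest `auc` per class and unweighted `macro_auc`.
#' @export
evaluate <- function(model, test_table) {
  probs <- predict(model, test_table, type = "prob")
  pred <- predict(model, test_table, type = "class")
  classification_metrics(test_table$class_label, pred, probs, model$classes)
}

feature_group_subsets <- function(table, subsets = NULL) {
  schema <- attr(table, "schema")
  cols <- feature_columns(table)
  if (is.null(schema)) return(list(all = cols))
  groups <- setNames(schema$group, schema$column)
  grp_of <- groups[cols]
  grp_of[is.na(grp_of)] <- "clinical"
  subsets <- subsets %||% list(
    all = unique(grp_of),
    shape_cardiac = c("shape", "cardiac", "clinical"),
    texture = c("glcm", "ngtdm", "first_order", "clinical"),
    cardiac = c("cardiac", "clinical"))
  out <- lapply(subsets, function(gs) cols[grp_of %in% gs])
  out[vapply(out, length, 0) > 0]
}

#' Nested cross-validated model selection and evaluation
#'
#' Outer loop: stratified folds; inner loop per outer-training set: grid
#' search over classifier configs x feature-class subsets selected by mean
#' inner-fold accuracy.  Outer test predictions are pooled into one confusion
#' matrix.  All preprocessing is fitted within training folds only;
#' everything is deterministic given `seed`.
#'
#' @param table A `feature_table` with >= 2 classes.
#' @param grid List of model configs (default [default_grid()]).
#' @param outer_folds,inner_folds Fold counts (default 8; reduced with a
#'   warning when a class is too small).
#' @param seed Integer seed.
#' @param subsets Named list of feature-group subsets to search (default:
#'   all / shape+cardiac / texture / cardiac, each plus clinical).
#' @return Object of class `cmr_cv`.
#' @export
nested_cv <- function(table, grid = default_grid(), outer_folds = 8,
                      inner_folds = 8, seed = 1L, subsets = NULL) {
  y <- factor(table$class_label)
  if (nlevels(y) < 2) stop2("nested_cv needs at least two classes")
  subs <- feature_group_subsets(table, subsets)
  candidates <- expand.grid(config = seq_along(grid), subset = seq_along(subs))
  of <- stratified_folds(y, outer_folds, seed)
  fold <- of$fold
  pooled_pred <- factor(rep(NA_character_, nrow(table)), levels = levels(y))
  pooled_prob <- matrix(NA_real_, nrow(table), nlevels(y),
                        dimnames = list(NULL, levels(y)))
  fold_scores <- numeric(of$k)
  selected <- vector("list", of$k)
  for (ko in seq_len(of$k)) {
    tr <- which(fold != ko); te <- which(fold == ko)
    inner <- stratified_folds(droplevels(y[tr]), inner_folds,
                              derive_seed(seed, ko))
    cand_acc <- numeric(nrow(candidates))
    for (ci in seq_len(nrow(candidates))) {
      cfg <- grid[[candidates$config[ci]]]
      feats <- subs[[candidates$subset[ci]]]
      accs <- numeric(inner$k)
      for (ki in seq_len(inner$k)) {
        itr <- tr[inner$fold != ki]; ite <- tr[inner$fold == ki]
        m <- fit_final(table[itr, , drop = FALSE], cfg,
                       seed = derive_seed(seed, ko * 1000 + ki),
                       features = feats)
        accs[ki] <- accuracy_score(y[ite],
                                   predict(m, table[ite, , drop = FALSE]))
      }
      cand_acc[ci] <- mean(accs)
    }
    best <- which.max(cand_acc)  # ties -> earlier (simpler) candidate
    cfg <- grid[[candidates$config[best]]]
    feats <- subs[[candidates$subset[best]]]
    m <- fit_final(table[tr, , drop = FALSE], cfg,
                   seed = derive_seed(seed, ko), features = feats)
    pooled_pred[te] <- predict(m, table[te, , drop = FALSE])
    pooled_prob[te, ] <- predict(m, table[te, , drop = FALSE], type = "prob")
    fold_scores[ko] <- accuracy_score(y[te], pooled_pred[te])
    selected[[ko]] <- list(family = cfg$family,
                           hyperparameters = cfg$hyperparameters,
                           feature_subset = names(subs)[candidates$subset[best]],
                           inner_accuracy = cand_acc[best])
  }
  metrics <- classification_metrics(y, pooled_pred, pooled_prob, levels(y))
  base::structure(list(fold_scores = fold_scores, selected = selected,
                       accuracy = metrics$accuracy, confusion = metrics$confusion,
                       precision = metrics$precision, recall = metrics$recall,
                       auc = metrics$auc, macro_auc = metrics$macro_auc,
                       outer_folds = of$k, seed = seed,
                       pooled_prob = pooled_prob, pooled_pred = pooled_pred),
                  class = "cmr_cv")
}

#' @export
print.cmr_cv <- function(x, ...) {
  cat(sprintf("<cmr_cv> %d outer folds; pooled accuracy %.3f, macro AUC %.3f\n",
              x$outer_folds, x$accuracy, x$macro_auc))
  fams <- vapply(x$selected, `[[`, "", "family")
  cat("  selected:", paste(sprintf("%s(%s)", fams,
      vapply(x$selected, `[[`, "", "feature_subset")), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cmr_cv <- function(object, ...) {
  cat(sprintf("Nested CV (%d outer folds, seed %d)\n", object$outer_folds,
              object$seed))
  cat(sprintf("Pooled accuracy: %.3f  macro AUC: %.3f\n", object$accuracy,
              object$macro_auc))
  cat("Confusion matrix:\n"); print(object$confusion)
  cat("Per-class precision:\n"); print(round(object$precision, 3))
  cat("Per-class recall:\n"); print(round(object$recall, 3))
  cat("Per-class AUC:\n"); print(round(object$auc, 3))
  invisible(object)
}

#' Permutation feature importance
#'
#' For each feature the column is shuffled (others fixed), the model is
#' rescored, and the importance is the baseline score minus the mean permuted
#' score over `repeats` shuffles.  A constant column is invariant under
#' shuffling, so its importance is exactly 0.
#'
#' The `log_lik` metric (mean predicted log-probability of the true class)
#' is margin-sensitive: on cohorts separable through several redundant
#' features, shuffling one of them erodes the probability margin even when
#' the predicted labels — and hence the accuracy — do not change, so it
#' yields an informative ranking where accuracy ties at zero.
#'
#' @param model A `cmr_model`.
#' @param table A `feature_table` to score on.
#' @param score_fn Optional custom score `(truth, pred) -> higher-is-better`.
#' @param metric `"accuracy"` (default) or `"log_lik"`; ignored when
#'   `score_fn` is given.
#' @param repeats Shuffles per feature (default 10).
#' @param seed Integer seed.
#' @return Object of class `importance_report`: data frame with `feature`,
#'   `baseline`, `mean_permuted`, `importance`, `sd`, ordered by importance.
#' @export
permutation_importance <- function(model, table, score_fn = NULL,
                                   metric = c("accuracy", "log_lik"),
                                   repeats = 10, seed = 1L) {
  metric <- match.arg(metric)
  truth <- table$class_label
  score <- if (!is.null(score_fn)) {
    function(tab) score_fn(truth, predict(model, tab))
  } else if (metric == "accuracy") {
    function(tab) accuracy_score(truth, predict(model, tab))
  } else {
    function(tab) {
      pr <- predict(model, tab, type = "prob")
      p <- pr[cbind(seq_along(truth), match(truth, colnames(pr)))]
      mean(log(pmax(p, 1e-12)))
    }
  }
  baseline <- score(table)
  feats <- model$features
  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[i]
    col <- table[[f]]
    if (length(unique(col[!is.na(col)])) <= 1) {
      rows[[i]] <- data.frame(feature = f, baseline = baseline,
                              mean_permuted = baseline, importance = 0, sd = 0)
      next
    }
    scores <- numeric(repeats)
    for (r in seq_len(repeats)) {
      set.seed(derive_seed(seed, i * 1000 + r))
      tp <- table
      tp[[f]] <- sample(col)
      scores[r] <- score(tp)
    }
    rows[[i]] <- data.frame(feature = f, baseline = baseline,
                            mean_permuted = mean(scores),
                            importance = baseline - mean(scores),
                            sd = sd(scores))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  base::structure(out, class = c("importance_report", "data.frame"))
}

#' Expert-in-the-loop improvement experiment
#'
#' Pipeline composition over a phantom cohort: corrupt a fraction of the
#' cases' segmentations, extract features, classify (nested CV), detect
#' outliers, simulate expert correction by restoring the true masks of all
#' flagged cases, re-extract the affected rows and re-classify.  Reports the
#' pooled CV accuracy before and after correction.
#'
#' @param cohort An uncorrupted phantom `cmr_cohort` (or one already
#'   corrupted by [generate_cohort()]; then use `corruption_rate = 0` and
#'   supply its `truth`).
#' @param truth Truth table from [generate_cohort()] (for already-corrupted
#'   cohorts its `true_masks` attribute is used for restoration).
#' @param corruption_rate Fraction of cases to corrupt here (default 0.1).
#' @param seed Integer seed.
#' @param grid,outer_folds,inner_folds,subsets Passed to [nested_cv()].
#' @param feature_set Feature preset for extraction (default `"fast"`).
#' @param z_threshold Outlier threshold for [feature_outliers()].
#' @return List with `accuracy_before`, `accuracy_after`, `corrected_cases`,
#'   `corrupted_cases`, `worklist`, and both `cmr_cv` objects.
#' @export
improvement_loop <- function(cohort, truth = NULL, corruption_rate = 0.1,
                             seed = 1L, grid = default_grid(), outer_folds = 8,
                             inner_folds = 8, subsets = NULL,
                             feature_set = "fast", z_threshold = 3.0) {
  cases <- cohort_cases(cohort)
  true_masks <- attr(truth, "true_masks") %||% list()
  corrupted <- names(true_masks)
  if (corruption_rate > 0) {
    for (i in seq_along(cases)) {
      set.seed(derive_seed(seed, 5000 + i))
      if (runif(1) < corruption_rate) {
        case <- cases[[i]]
        sess <- latest_session(case)
        kind <- sample(c("slice_shift", "mask_dilate", "mask_dropout"), 1)
        new_sess <- inject_corruption(sess, kind, seed = derive_seed(seed, 6000 + i))
        true_masks[[case$case_id]] <- sess$mask
        case$sessions <- setNames(list(new_sess), new_sess$session_id)
        cases[[i]] <- case
        cohort <- set_cohort_case(cohort, case)
        corrupted <- c(corrupted, case$case_id)
      }
    }
  }
  table_before <- extract_feature_table(cohort, feature_set)
  cv_before <- nested_cv(table_before, grid, outer_folds, inner_folds, seed,
                         subsets)
  rep_feat <- feature_outliers(table_before, z_threshold = z_threshold)
  rep_geom <- cohort_misalignment(cohort)
  worklist <- build_worklist(rep_feat, rep_geom)
  table_after <- table_before
  corrected <- character()
  for (cid in worklist$case_id) {
    if (!cid %in% names(true_masks)) next  # flagged but not corrupted: no-op
    case <- cohort_cases(cohort)[[cid]]
    case <- add_session(case, true_masks[[cid]], "corrected",
                        per_contour_corrected = data.frame(
                          phase = 1L, slice = 1L, structure = "lv_epi",
                          corrected = TRUE))
    cohort <- set_cohort_case(cohort, case)
    new_row <- feature_row(case, latest_session(case), feature_set,
                           c("height_cm", "weight_kg"))
    table_after[table_after$case_id == cid, ] <- new_row
    corrected <- c(corrected, cid)
  }
  cv_after <- nested_cv(table_after, grid, outer_folds, inner_folds, seed,
                        subsets)
  list(accuracy_before = cv_before$accuracy, accuracy_after = cv_after$accuracy,
       corrected_cases = corrected, corrupted_cases = unique(corrupted),
       worklist = worklist, cv_before = cv_before, cv_after = cv_after)
}
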