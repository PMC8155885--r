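# Classifier configurations, stratified k-fold cross-validation,
# confusion-matrix metrics, ROC curves and the ABC vs no-ABC comparison.
#
# The classifiers themselves are off-the-shelf (rpart, randomForest,
# class::knn, e1071::svm); this module owns the named configurations,
# the folding, the metrics and the statistics. "fast" is the positive
# class throughout.

#' Named classifier configurations
#'
#' Families and variants: decision trees limited to at most 100/20/3
#' splits (fine/medium/coarse); a random forest; kNN with 1/3/20
#' neighbors (fine/medium/coarse, Euclidean = Minkowski with exponent 2)
#' plus a cosine-distance variant (k = 10); SVMs with linear, quadratic
#' (`"polynomial"`), cubic and Gaussian-RBF kernels.
#'
#' @param family `"decision_tree"`, `"random_forest"`, `"knn"` or `"svm"`.
#' @param variant named configuration within the family (see Details);
#'   `random_forest` has a single `"default"` variant (100 trees).
#' @return A `classifier_spec` list with resolved hyperparameters.
#' @export
classifier_spec <- function(family = c("decision_tree", "random_forest",
                                       "knn", "svm"),
                            variant = NULL) {
  family <- match.arg(family)
  variants <- switch(family,
    decision_tree = list(fine = list(max_splits = 100L),
                         medium = list(max_splits = 20L),
                         coarse = list(max_splits = 3L)),
    random_forest = list(default = list(ntree = 100L)),
    knn = list(fine = list(k = 1L, distance = "euclidean"),
               medium = list(k = 3L, distance = "euclidean"),
               coarse = list(k = 20L, distance = "euclidean"),
               cosine = list(k = 10L, distance = "cosine")),
    svm = list(linear = list(kernel = "linear", degree = 1L),
               polynomial = list(kernel = "polynomial", degree = 2L),
               cubic = list(kernel = "polynomial", degree = 3L),
               rbf = list(kernel = "radial", degree = NA_integer_)))
  if (is.null(variant)) variant <- names(variants)[1L]
  if (!variant %in% names(variants))
    stop("unknown ", family, " variant '", variant, "'; available: ",
         paste(names(variants), collapse = ", "))
  structure(c(list(family = family, variant = variant), variants[[variant]]),
            class = "classifier_spec")
}

#' All twelve classifier configurations
#' @return Named list of [classifier_spec()]s in the order decision trees
#'   (fine/medium/coarse), random forest, kNN (fine/medium/coarse/cosine),
#'   SVM (linear/polynomial/cubic/rbf).
#' @export
all_classifiers <- function() {
  specs <- list(
    tree_fine = classifier_spec("decision_tree", "fine"),
    tree_medium = classifier_spec("decision_tree", "medium"),
    tree_coarse = classifier_spec("decision_tree", "coarse"),
    random_forest = classifier_spec("random_forest"),
    knn_fine = classifier_spec("knn", "fine"),
    knn_medium = classifier_spec("knn", "medium"),
    knn_coarse = classifier_spec("knn", "coarse"),
    knn_cosine = classifier_spec("knn", "cosine"),
    svm_linear = classifier_spec("svm", "linear"),
    svm_polynomial = classifier_spec("svm", "polynomial"),
    svm_cubic = classifier_spec("svm", "cubic"),
    svm_rbf = classifier_spec("svm", "rbf"))
  specs
}

# Per-column z-scoring fitted on the training fold only; constant
# columns get scale 1 so they map to 0. Distance- and margin-based
# learners (knn, svm) are scale-sensitive; trees are not standardized.
standardize_pair <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2L, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(train = sweep(sweep(x_train, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(x_test, 2L, mu), 2L, sdv, "/"))
}

l2_normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

# Train on (x_train, y_train), predict classes and a continuous
# fast-score on x_test. y levels are c("fast", "slow").
train_predict <- function(spec, x_train, y_train, x_test) {
  if (spec$family %in% c("knn", "svm")) {
    s <- standardize_pair(x_train, x_test)
    x_train <- s$train
    x_test <- s$test
  }
  if (spec$family == "decision_tree") {
    df_train <- data.frame(y = y_train, x_train, check.names = FALSE)
    df_test <- data.frame(x_test, check.names = FALSE)
    fit <- rpart::rpart(y ~ ., data = df_train, method = "class",
                        control = rpart::rpart.control(cp = 0, xval = 0L,
                                                       minsplit = 2L,
                                                       minbucket = 1L))
    cp_tab <- fit$cptable
    ok <- cp_tab[, "nsplit"] <= spec$max_splits
    if (!all(ok)) {
      cp_row <- max(which(ok))
      fit <- rpart::prune(fit, cp = cp_tab[cp_row, "CP"])
    }
    prob <- predict(fit, df_test, type = "prob")[, "fast"]
    cls <- factor(ifelse(prob >= 0.5, "fast", "slow"), levels = levels(y_train))
  } else if (spec$family == "random_forest") {
    fit <- randomForest::randomForest(x_train, y_train, ntree = spec$ntree)
    prob <- predict(fit, x_test, type = "prob")[, "fast"]
    cls <- predict(fit, x_test)
  } else if (spec$family == "knn") {
    if (spec$distance == "cosine") {
      # cosine distance ranks neighbors identically to Euclidean distance
      # on L2-normalized rows
      x_train <- l2_normalize_rows(x_train)
      x_test <- l2_normalize_rows(x_test)
    }
    cls <- class::knn(x_train, x_test, y_train, k = spec$k, prob = TRUE)
    win <- attr(cls, "prob")
    prob <- ifelse(cls == "fast", win, 1 - win)
  } else {
    fit <- e1071::svm(x_train, y_train, kernel = spec$kernel,
                      degree = if (is.na(spec$degree)) 3L else spec$degree,
                      coef0 = 1, scale = FALSE)
    pred <- predict(fit, x_test, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    # orient the margin so larger means more "fast"
    if (!grepl("^fast", colnames(attr(pred, "decision.values"))[1L])) dv <- -dv
    prob <- dv
    cls <- pred
  }
  list(class = factor(as.character(cls), levels = c("fast", "slow")),
       score = as.numeric(prob))
}

#' Stratified fold assignment
#'
#' Rows of each class are shuffled (seeded) and dealt round-robin over
#' `k` folds, so every fold contains both classes whenever each class
#' has at least `k` members.
#'
#' @param y factor of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`, one per row.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  if (any(table(y) < k))
    stop("stratification error: a class has fewer than k = ", k, " members")
  set.seed(seed)
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated accuracy
#'
#' Mean held-out accuracy over `k` stratified folds. This is the ABC
#' fitness function. Deterministic given `seed` (or an explicit `folds`
#' assignment): fold splits and any classifier randomness derive from it.
#'
#' @param table a `feature_table`.
#' @param spec a [classifier_spec()].
#' @param k folds (default 5).
#' @param seed integer seed used for fold assignment and classifier RNG.
#' @param folds optional precomputed fold vector (overrides `seed` for
#'   the assignment).
#' @return Accuracy fraction in `[0, 1]`.
#' @export
cv_accuracy <- function(table, spec, k = 5L, seed = 1L, folds = NULL) {
  y <- table$label
  if (is.null(folds)) folds <- stratified_folds(y, k = k, seed = seed)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- folds == f
    set.seed(seed * 131L + f)  # classifier randomness (e.g. forest bootstrap)
    pred <- train_predict(spec, table$x[!te, , drop = FALSE], y[!te],
                          table$x[te, , drop = FALSE])
    acc[f] <- mean(pred$class == y[te])
  }
  mean(acc)
}

#' Confusion-matrix metrics
#'
#' `fast` is the positive class: accuracy = (TP+TN)/total, sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP).
#'
#' @param tp,fp,tn,fn integer counts.
#' @return Named list: `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

# One repeat: k-fold CV, predictions pooled across held-out folds into a
# single confusion matrix (the default reading; per-fold means differ
# only in weighting when folds are unequal).
cv_confusion <- function(table, spec, k, seed) {
  y <- table$label
  folds <- stratified_folds(y, k = k, seed = seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  score <- numeric(length(y))
  for (f in seq_len(k)) {
    te <- folds == f
    set.seed(seed * 131L + f)
    p <- train_predict(spec, table$x[!te, , drop = FALSE], y[!te],
                       table$x[te, , drop = FALSE])
    pred[te] <- p$class
    score[te] <- p$score
  }
  list(confusion = confusion_metrics(tp = sum(pred == "fast" & y == "fast"),
                                     fp = sum(pred == "fast" & y == "slow"),
                                     tn = sum(pred == "slow" & y == "slow"),
                                     fn = sum(pred == "slow" & y == "fast")),
       score = score, truth = y)
}

#' Repeated cross-validated evaluation
#'
#' Runs `repeats` independent CV evaluations with derived seeds and
#' summarizes the per-repeat accuracy/sensitivity/specificity with the
#' five-number quantile layout (best, upper quartile, median, lower
#' quartile, worst) plus mean and SD. The confusion matrix of the
#' median-accuracy repeat is reported.
#'
#' @inheritParams cv_accuracy
#' @param repeats number of repeats (default 5).
#' @return An `eval_result`: `per_repeat` data frame, `summary` (named
#'   numeric), `confusion` (median repeat), `spec`.
#' @export
evaluate_full <- function(table, spec, k = 5L, repeats = 5L, seed = 1L) {
  if (repeats < 1L) stop("`repeats` must be >= 1")
  runs <- lapply(seq_len(repeats), function(i)
    cv_confusion(table, spec, k = k, seed = seed + 1000L * (i - 1L)))
  per <- do.call(rbind, lapply(seq_len(repeats), function(i) {
    cm <- runs[[i]]$confusion
    data.frame(repeat_ = i, accuracy = cm$accuracy,
               sensitivity = cm$sensitivity, specificity = cm$specificity)
  }))
  acc <- per$accuracy
  med_i <- order(acc)[ceiling(length(acc) / 2)]
  summary <- c(best = max(acc),
               upper_quartile = as.numeric(quantile(acc, 0.75)),
               median = median(acc),
               lower_quartile = as.numeric(quantile(acc, 0.25)),
               worst = min(acc),
               mean = mean(acc), sd = if (repeats > 1L) sd(acc) else 0)
  structure(list(per_repeat = per, summary = summary,
                 confusion = runs[[med_i]]$confusion, spec = spec,
                 k = k, repeats = repeats, seed = seed),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s/%s, %d-fold CV x %d repeats\n",
              x$spec$family, x$spec$variant, x$k, x$repeats))
  print(round(x$summary, 4))
  cm <- x$confusion
  cat(sprintf("median-repeat confusion: TP %d FP %d TN %d FN %d (acc %.3f, sens %.3f, spec %.3f)\n",
              cm$tp, cm$fp, cm$tn, cm$fn, cm$accuracy, cm$sensitivity,
              cm$specificity))
  invisible(x)
}

#' ROC curve from pooled cross-validated scores
#'
#' Held-out scores are pooled across folds and the threshold swept over
#' the unique score values; the curve starts at (0,0) and ends at (1,1).
#'
#' @inheritParams cv_accuracy
#' @return Data frame with columns `fpr`, `tpr` (and the implied `auc`
#'   as an attribute).
#' @export
roc_curve <- function(table, spec, k = 5L, seed = 1L) {
  run <- cv_confusion(table, spec, k = k, seed = seed)
  roc_points(run$score, run$truth)
}

roc_points <- function(score, truth) {
  pos <- truth == "fast"
  np <- sum(pos)
  nn <- sum(!pos)
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  # one point per unique threshold (last index of each tied score block)
  last <- c(diff(score[ord]) != 0, TRUE)
  df <- data.frame(fpr = c(0, fp[last] / nn, 1), tpr = c(0, tp[last] / np, 1))
  df <- unique(df)
  auc <- sum(diff(df$fpr) * (head(df$tpr, -1) + df$tpr[-1]) / 2)
  attr(df, "auc") <- auc
  df
}

#' Median ROC curve over repeated cross-validations
#'
#' Evaluates [roc_curve()] with `repeats` derived seeds, interpolates
#' each curve on a common FPR grid and takes the pointwise median TPR.
#'
#' @inheritParams evaluate_full
#' @param grid FPR grid for interpolation (default 101 points).
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_median <- function(table, spec, k = 5L, repeats = 5L, seed = 1L,
                       grid = seq(0, 1, length.out = 101L)) {
  tprs <- vapply(seq_len(repeats), function(i) {
    df <- roc_curve(table, spec, k = k, seed = seed + 1000L * (i - 1L))
    approx(df$fpr, df$tpr, xout = grid, ties = max)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = apply(tprs, 1L, median))
}

#' Compare per-repeat accuracies with and without ABC selection
#'
#' Two-sided t-test of the per-repeat metric values. `"paired"` (df =
#' n - 1) is the default: the repeats share derived fold seeds, and the
#' reference results print df = 4 for n = 5. `"independent"` uses the
#' pooled-variance test (df = 2n - 2).
#'
#' @param with_abc,without_abc numeric vectors of per-repeat values,
#'   equal length >= 2.
#' @param mode `"paired"` or `"independent"`.
#' @return List with `t`, `df`, `p`, `mean_with`, `mean_without`, `mode`.
#' @export
compare_abc <- function(with_abc, without_abc,
                        mode = c("paired", "independent")) {
  mode <- match.arg(mode)
  if (length(with_abc) != length(without_abc))
    stop("per-repeat vectors must have equal length")
  if (length(with_abc) < 2L) stop("need at least 2 repeats per condition")
  if (mode == "paired" && sd(with_abc - without_abc) == 0) {
    # constant pairwise differences: t.test errors on 0 variance
    d <- mean(with_abc - without_abc)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(with_abc) - 1L, p = if (d == 0) 1 else 0,
                mean_with = mean(with_abc), mean_without = mean(without_abc),
                mode = mode))
  }
  ht <- t.test(with_abc, without_abc, paired = (mode == "paired"),
               var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_with = mean(with_abc),
       mean_without = mean(without_abc), mode = mode)
}
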