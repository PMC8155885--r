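test_that("classifier specs resolve the named configurations", {
  expect_equal(classifier_spec("decision_tree", "fine")$max_splits, 100L)
  expect_equal(classifier_spec("decision_tree", "coarse")$max_splits, 3L)
  expect_equal(classifier_spec("knn", "fine")$k, 1L)
  expect_equal(classifier_spec("knn", "coarse")$k, 20L)
  expect_equal(classifier_spec("knn", "cosine")$distance, "cosine")
  expect_equal(classifier_spec("svm", "polynomial")$degree, 2L)
  expect_equal(classifier_spec("svm", "cubic")$degree, 3L)
  expect_error(classifier_spec("knn", "huge"), "variant")
  expect_length(all_classifiers(), 12L)
})

test_that("confusion metrics satisfy their identities", {
  m <- confusion_metrics(tp = 7, fn = 2, tn = 5, fp = 4)
  expect_equal(m$accuracy, 12 / 18)
  expect_equal(round(m$accuracy, 3), 0.667)
  expect_equal(round(m$sensitivity, 3), 0.778)
  expect_equal(round(m$specificity, 3), 0.556)
  perfect <- confusion_metrics(tp = 9, fn = 0, tn = 9, fp = 0)
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  set.seed(30)
  for (i in 1:50) {
    cm <- as.list(sample(0:40, 4, replace = TRUE) + 1)
    names(cm) <- c("tp", "fp", "tn", "fn")
    m <- do.call(confusion_metrics, cm)
    expect_equal(m$accuracy, (cm$tp + cm$tn) / Reduce(`+`, cm))
    expect_equal(m$sensitivity, cm$tp / (cm$tp + cm$fn))
    expect_equal(m$specificity, cm$tn / (cm$tn + cm$fp))
    expect_true(all(unlist(m[c("accuracy", "sensitivity", "specificity")]) >= 0))
    expect_true(all(unlist(m[c("accuracy", "sensitivity", "specificity")]) <= 1))
  }
})

separable_table <- function(n_per_class = 30, seed = 1) {
  sp <- feature_space(channels = "C1", bands = c("x", "y"))
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * 4, mean = 5), ncol = 4),
             matrix(rnorm(n_per_class * 4, mean = -5), ncol = 4))
  feature_table(x, rep(c("fast", "slow"), each = n_per_class), sp, 2)
}

test_that("perfectly separated clusters reach accuracy 1 for every family", {
  tbl <- separable_table()
  for (spec in all_classifiers()[c("tree_medium", "random_forest",
                                   "knn_medium", "knn_cosine",
                                   "svm_linear", "svm_rbf")]) {
    expect_equal(cv_accuracy(tbl, spec, seed = 1), 1.0)
  }
})

test_that("cross-validation is deterministic and fold-permutation invariant", {
  sp <- toy_space()
  tbl <- gen_feature_table(sp, informative = 1:2, n_per_class = 30,
                           tau_max = 3, seed = 3)
  spec <- classifier_spec("knn", "medium")
  expect_identical(cv_accuracy(tbl, spec, seed = 5),
                   cv_accuracy(tbl, spec, seed = 5))
  # permuting rows together with their fold assignment leaves accuracy
  # unchanged
  folds <- stratified_folds(tbl$label, k = 5, seed = 5)
  perm <- sample(nrow(tbl$x))
  tblp <- tbl
  tblp$x <- tbl$x[perm, , drop = FALSE]
  tblp$label <- tbl$label[perm]
  expect_equal(cv_accuracy(tbl, spec, folds = folds),
               cv_accuracy(tblp, spec, folds = folds[perm]))
})

test_that("stratified folds always contain both classes", {
  y <- factor(rep(c("fast", "slow"), c(40, 15)), levels = c("fast", "slow"))
  folds <- stratified_folds(y, k = 5, seed = 2)
  for (f in 1:5) expect_setequal(as.character(unique(y[folds == f])),
                                 c("fast", "slow"))
  expect_error(stratified_folds(factor(rep(c("fast", "slow"), c(3, 40)),
                                       levels = c("fast", "slow")), k = 5),
               "stratification error")
})

test_that("permuted labels give chance-level accuracy", {
  sp <- feature_space(channels = "C1", bands = c("x", "y"))
  inside <- vapply(1:20, function(s) {
    set.seed(s + 400)
    x <- matrix(rnorm(500 * 4), ncol = 4)
    lab <- sample(rep(c("fast", "slow"), each = 250))
    tbl <- feature_table(x, lab, sp, 2)
    acc <- cv_accuracy(tbl, classifier_spec("knn", "medium"), seed = s)
    acc >= 0.4 && acc <= 0.6
  }, TRUE)
  expect_gte(mean(inside), 0.9)
})

test_that("repeated evaluation summarizes per-repeat metrics", {
  tbl <- separable_table(20, seed = 6)
  ev <- evaluate_full(tbl, classifier_spec("knn", "fine"), repeats = 3,
                      seed = 2)
  expect_equal(nrow(ev$per_repeat), 3L)
  expect_equal(ev$summary[["median"]], 1)
  expect_equal(ev$confusion$fp + ev$confusion$tn, 20)
  # single repeat: degenerate summary
  ev1 <- evaluate_full(tbl, classifier_spec("knn", "fine"), repeats = 1,
                       seed = 2)
  expect_equal(ev1$summary[["best"]], ev1$summary[["median"]])
  expect_equal(ev1$summary[["sd"]], 0)
})

test_that("ROC curves span (0,0) to (1,1) and are monotone", {
  tbl <- separable_table(20, seed = 7)
  roc <- roc_curve(tbl, classifier_spec("knn", "coarse"), seed = 1)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_false(is.unsorted(roc$fpr))
  expect_false(is.unsorted(roc$tpr))
  # perfect separation passes through (0, 1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(attr(roc, "auc"), 1)
})

test_that("degenerate constant scores give the diagonal", {
  df <- mseabc:::roc_points(rep(0.5, 10),
                            factor(rep(c("fast", "slow"), 5),
                                   levels = c("fast", "slow")))
  expect_equal(df, data.frame(fpr = c(0, 1), tpr = c(0, 1)),
               ignore_attr = TRUE)
  expect_equal(attr(df, "auc"), 0.5)
})

test_that("pooled-score AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  truth <- factor(sample(rep(c("fast", "slow"), 50)),
                  levels = c("fast", "slow"))
  score <- rnorm(100) + (truth == "fast") * 0.8
  mine <- attr(mseabc:::roc_points(score, truth), "auc")
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score, levels = c("slow", "fast"),
    direction = "<"))))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("random scores give chance-level AUC", {
  set.seed(32)
  aucs <- replicate(20, {
    truth <- factor(sample(rep(c("fast", "slow"), 100)),
                    levels = c("fast", "slow"))
    attr(mseabc:::roc_points(rnorm(200), truth), "auc")
  })
  expect_gte(mean(aucs >= 0.4 & aucs <= 0.6), 0.9)
})

test_that("the ABC comparison t-test matches a textbook recomputation", {
  with_abc <- c(0.86, 0.85, 0.85, 0.84, 0.85)
  without <- c(0.77, 0.78, 0.78, 0.76, 0.78)
  res <- compare_abc(with_abc, without, mode = "paired")
  d <- with_abc - without
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 4))
  # independent mode: pooled variance, df = 2n - 2
  res_i <- compare_abc(with_abc, without, mode = "independent")
  sp2 <- (4 * var(with_abc) + 4 * var(without)) / 8
  expect_equal(res_i$t, (mean(with_abc) - mean(without)) /
                 sqrt(sp2 * (2 / 5)))
  expect_equal(res_i$df, 8)
  # identical samples: t = 0, p = 1
  same <- compare_abc(c(0.8, 0.8, 0.9), c(0.8, 0.8, 0.9))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(compare_abc(0.9, 0.8), "at least 2")
})
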