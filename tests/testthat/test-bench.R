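test_that("stratified folds partition indices with per-fold class balance", {
  labels <- rep(c("a", "b"), each = 5)
  folds <- stratified_folds(labels, cv_plan(k = 5))
  expect_equal(sort(unlist(folds)), 1:10)
  for (f in folds) expect_equal(sort(labels[f]), c("a", "b"))

  # 97 samples split 60/37: per-fold counts within 1 of proportionality,
  # verified by enumerating the fold assignment
  labels2 <- rep(c("x", "y"), times = c(60, 37))
  folds2 <- stratified_folds(labels2, cv_plan(k = 5))
  expect_equal(sort(unlist(folds2)), 1:97)
  expect_true(all(!duplicated(unlist(folds2))))
  for (f in folds2) {
    cx <- sum(labels2[f] == "x"); cy <- sum(labels2[f] == "y")
    expect_lte(abs(cx - 60 / 5), 1)
    expect_lte(abs(cy - 37 / 5), 1)
  }
  expect_error(stratified_folds(c(rep("a", 10), "b"), cv_plan(k = 5)),
               "at least k")
})

test_that("metric suite matches hand computations", {
  perfect <- metric_suite(c(0, 1, 0, 1), c(0, 1, 0, 1),
                          y_score = cbind(`0` = c(.9, .1, .8, .2),
                                          `1` = c(.1, .9, .2, .8)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  onesided <- metric_suite(rep(c("a", "b"), each = 5), rep("a", 10))
  expect_equal(onesided$accuracy, 0.5)
  expect_equal(onesided$recall, 0.5)  # macro: recall 1 for a, 0 for b
  expect_true(is.na(onesided$auc))

  # realize the fixture confusion matrix TP 3, FP 1, FN 2, TN 4
  y_true <- c(rep("pos", 5), rep("neg", 5))
  y_pred <- c("pos", "pos", "pos", "neg", "neg",
              "pos", "neg", "neg", "neg", "neg")
  m <- metric_suite(y_true, y_pred)
  expect_equal(m$confusion["pos", "pos"], 3)
  expect_equal(m$confusion["pos", "neg"], 2)
  expect_equal(m$confusion["neg", "pos"], 1)
  # precision/recall of the positive class
  expect_equal(3 / (3 + 1), 0.75)
  expect_equal(unname(m$confusion["pos", "pos"] / sum(m$confusion["pos", ])), 0.6)
  expect_error(metric_suite(1:3, 1:4), "length mismatch")
})

test_that("rank-based AUC equals trapezoidal ROC integration", {
  set.seed(11)
  score <- stats::runif(50)
  pos <- stats::runif(50) < 0.4
  # independent oracle: all pairwise comparisons
  pairs <- expand.grid(i = which(pos), j = which(!pos))
  auc_pairs <- mean(ifelse(score[pairs$i] > score[pairs$j], 1,
                           ifelse(score[pairs$i] == score[pairs$j], 0.5, 0)))
  expect_equal(emglab:::binary_auc(score, pos), auc_pairs)
})

test_that("cross-validation is deterministic and aggregates confusions correctly", {
  sf <- study_features(1)
  labels <- auto_label(sf$features)$labels
  r1 <- evaluate(classifier_registry("knn"), sf$features, labels, cv_plan())
  r2 <- evaluate(classifier_registry("knn"), sf$features, labels, cv_plan())
  expect_identical(r1$per_fold, r2$per_fold)
  expect_equal(sum(r1$confusion), length(labels))
  expect_equal(as.integer(rowSums(r1$confusion)), as.integer(table(labels)))
  expect_error(evaluate(classifier_registry("knn"), sf$features,
                        rep(1, nrow(sf$features))), "2 classes")
})

test_that("permuted labels drive AUC to chance level", {
  sf <- study_features(1)
  set.seed(12)
  perm <- sample(auto_label(sf$features)$labels)
  r <- evaluate(classifier_registry("lda"), sf$features, perm, cv_plan())
  expect_gte(r$mean[["auc"]], 0.30)
  expect_lte(r$mean[["auc"]], 0.70)
})

test_that("every registry classifier separates the default synthetic task", {
  sf <- study_features(1)
  labels <- auto_label(sf$features)$labels
  for (nm in classifier_registry("all")) {
    r <- suppressWarnings(
      evaluate(classifier_registry(nm), sf$features, labels, cv_plan()))
    expect_gte(r$mean[["accuracy"]], 0.95)
  }
  expect_equal(classifier_registry("lightgbm")$name, "gradient_boosting")
  expect_error(classifier_registry("nonesuch"), "unknown classifier")
})

test_that("three-class synthetic profiles are well separated and ordered", {
  mc <- multiclass_dataset(n_per_class = 40, seed = 2)
  expect_equal(as.integer(table(mc$labels)), rep(40L, 3))
  rms_by <- tapply(mc$features$rms, mc$labels, mean)
  expect_true(rms_by[["resting"]] < rms_by[["five_finger"]])
  expect_true(rms_by[["resting"]] < rms_by[["individual_finger"]])
  r <- evaluate(classifier_registry("random_forest"), mc$features, mc$labels,
                cv_plan())
  expect_gte(r$mean[["accuracy"]], 0.95)
})
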