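#' Classifier benchmarking under stratified cross-validation
#'
#' A fixed registry of classifier configurations (decision tree, random
#' forest, gradient boosting, RBF-SVM, k-NN, LDA, QDA and a hard-voting
#' ensemble) evaluated with stratified k-fold cross-validation and the
#' standard metric suite (accuracy, macro precision/recall/F1, AUC,
#' aggregated confusion matrix). Fold assignment is shuffled with a fixed
#' seed (default 42) for reproducibility.
#'
#' @name bench
NULL

#' Classifier registry
#'
#' Fixed hyperparameter configurations: decision tree (max depth 10, min
#' split 5), random forest (50 trees, Gini, bootstrap), gradient boosting
#' (learning rate 0.1, max depth 3), SVM (RBF kernel, C = 1, scaled
#' gamma), k-NN (k = 3, Euclidean, uniform weights), LDA and QDA, and a
#' hard-voting ensemble of {random_forest, gradient_boosting, svm, knn}.
#' `lightgbm` is accepted as an alias of `gradient_boosting`.
#'
#' @param name Registry name, or `"all"` for the full list of names.
#' @return An object of class `classifier_config` (or character vector
#'   for `"all"`).
#' @export
classifier_registry <- function(name) {
  known <- c("decision_tree", "random_forest", "gradient_boosting",
             "svm", "knn", "lda", "qda", "voting_ensemble")
  if (identical(name, "all")) return(known)
  if (identical(name, "lightgbm")) name <- "gradient_boosting"
  if (!name %in% known)
    stop("unknown classifier '", name, "'; known: ",
         paste(known, collapse = ", "))
  hp <- switch(name,
    decision_tree = list(max_depth = 10, min_samples_split = 5),
    random_forest = list(n_trees = 50),
    gradient_boosting = list(learning_rate = 0.1, max_depth = 3,
                             n_rounds = 100),
    svm = list(kernel = "radial", cost = 1.0, gamma = "scale"),
    knn = list(k = 3, metric = "euclidean", weights = "uniform"),
    lda = list(solver = "svd"),
    qda = list(solver = "svd"),
    voting_ensemble = list(members = c("random_forest", "gradient_boosting",
                                       "svm", "knn"), vote = "hard"))
  structure(list(name = name, hyperparams = hp),
            class = "classifier_config")
}

#' Cross-validation plan
#'
#' @param k Number of folds (default 5).
#' @param seed Shuffle seed (default 42).
#' @return An object of class `cv_plan` (always stratified).
#' @export
cv_plan <- function(k = 5, seed = 42) {
  if (k < 2) stop("k must be >= 2")
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 stratified = TRUE),
            class = "cv_plan")
}

#' Stratified fold assignment
#'
#' Indices are shuffled with the plan seed, then each class's members are
#' dealt round-robin to the k folds, so per-fold class counts differ from
#' exact proportionality by at most one.
#'
#' @param labels Class labels.
#' @param plan A [cv_plan()].
#' @return List of k integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, plan = cv_plan()) {
  stopifnot(inherits(plan, "cv_plan"))
  tab <- table(labels)
  if (any(tab < plan$k))
    stop("every class needs at least k = ", plan$k, " members; got ",
         paste(names(tab)[tab < plan$k], collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(plan$seed)
  perm <- sample(seq_along(labels))
  folds <- vector("list", plan$k)
  for (cl in names(tab)) {
    idx <- perm[labels[perm] == cl]
    assign_to <- rep_len(seq_len(plan$k), length(idx))
    for (f in seq_len(plan$k))
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
  }
  lapply(folds, sort)
}

# Greedily keep a maximal set of columns whose (optionally per-class)
# submatrices are numerically full rank and non-constant.
full_rank_columns <- function(x, y, per_class = FALSE, tol = 1e-7) {
  x <- as.matrix(x)
  groups <- if (per_class) split(seq_len(nrow(x)), y)
            else list(seq_len(nrow(x)))
  keep <- integer(0)
  for (j in seq_len(ncol(x))) {
    cand <- c(keep, j)
    ok <- all(vapply(groups, function(idx) {
      sub <- x[idx, cand, drop = FALSE]
      if (any(apply(sub, 2, stats::sd) < tol)) return(FALSE)
      qr(scale(sub), tol = tol)$rank == length(cand)
    }, logical(1)))
    if (ok) keep <- cand
  }
  keep
}

# Fit one registry classifier and predict labels + scores on new data.
# Scores are per-class probabilities (or vote fractions for knn/voting).
fit_predict <- function(config, x_train, y_train, x_test, seed = 0L) {
  y_train <- factor(y_train)
  lev <- levels(y_train)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  name <- config$name
  hp <- config$hyperparams
  if (name == "decision_tree") {
    fit <- rpart::rpart(y ~ ., data = data.frame(x_train, y = y_train),
                        method = "class",
                        control = rpart::rpart.control(
                          maxdepth = hp$max_depth,
                          minsplit = hp$min_samples_split, cp = 0))
    prob <- stats::predict(fit, data.frame(x_test), type = "prob")
  } else if (name == "random_forest") {
    fit <- randomForest::randomForest(x = x_train, y = y_train,
                                      ntree = hp$n_trees)
    prob <- stats::predict(fit, x_test, type = "prob")
  } else if (name == "gradient_boosting") {
    ytr <- as.integer(y_train) - 1L
    nc <- length(lev)
    params <- list(eta = hp$learning_rate, max_depth = hp$max_depth,
                   nthread = 1)
    dtrain <- xgboost::xgb.DMatrix(as.matrix(x_train), label = ytr)
    dtest <- xgboost::xgb.DMatrix(as.matrix(x_test))
    if (nc == 2) {
      params$objective <- "binary:logistic"
      fit <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hp$n_rounds, verbose = 0)
      p1 <- stats::predict(fit, dtest)
      prob <- cbind(1 - p1, p1)
    } else {
      params$objective <- "multi:softprob"
      params$num_class <- nc
      fit <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hp$n_rounds, verbose = 0)
      prob <- matrix(stats::predict(fit, dtest), ncol = nc, byrow = TRUE)
    }
    colnames(prob) <- lev
  } else if (name == "svm") {
    fit <- e1071::svm(x = x_train, y = y_train, kernel = hp$kernel,
                      cost = hp$cost, probability = TRUE)
    pr <- stats::predict(fit, x_test, probability = TRUE)
    prob <- attr(pr, "probabilities")[, lev, drop = FALSE]
  } else if (name == "knn") {
    pr <- class::knn(train = as.matrix(x_train), test = as.matrix(x_test),
                     cl = y_train, k = hp$k, prob = TRUE)
    # knn reports only the winning-vote fraction; spread it over classes
    frac <- attr(pr, "prob")
    prob <- matrix((1 - frac) / max(1, length(lev) - 1),
                   nrow = length(pr), ncol = length(lev),
                   dimnames = list(NULL, lev))
    prob[cbind(seq_along(pr), match(as.character(pr), lev))] <- frac
  } else if (name %in% c("lda", "qda")) {
    # discriminant analysis needs full-rank class covariances: drop
    # exactly dependent columns (range = max - min, variance = std^2,
    # energy = n * rms^2) and columns constant within some class
    keep <- full_rank_columns(x_train, y_train,
                              per_class = identical(name, "qda"))
    fit <- if (name == "lda") MASS::lda(x_train[, keep, drop = FALSE],
                                        grouping = y_train)
           else MASS::qda(x_train[, keep, drop = FALSE],
                          grouping = y_train)
    prob <- stats::predict(fit,
                           x_test[, keep, drop = FALSE])$posterior[, lev,
                                                                   drop = FALSE]
  } else if (name == "voting_ensemble") {
    votes <- sapply(hp$members, function(m) {
      as.character(fit_predict(classifier_registry(m), x_train, y_train,
                               x_test, seed = seed)$predicted)
    })
    votes <- matrix(votes, ncol = length(hp$members))
    prob <- t(apply(votes, 1, function(v) {
      tabulate(factor(v, levels = lev), nbins = length(lev)) / length(v)
    }))
    colnames(prob) <- lev
  } else stop("unhandled classifier: ", name)
  pred <- factor(lev[max.col(prob, ties.method = "first")], levels = lev)
  list(predicted = pred, scores = prob, levels = lev)
}

#' Metric suite
#'
#' Accuracy, macro-averaged precision/recall/F1, the confusion matrix,
#' and AUC: trapezoidal (rank-based) for binary tasks, one-vs-rest macro
#' for multiclass. Per-class precision/recall with an empty denominator
#' count as 0 in the macro average.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param y_score Optional score matrix (columns = classes) for AUC.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `auc`
#'   (NA when scores are absent) and `confusion`.
#' @export
metric_suite <- function(y_true, y_pred, y_score = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  lev <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  yt <- factor(y_true, levels = lev)
  yp <- factor(y_pred, levels = lev)
  cm <- table(true = yt, predicted = yp)
  prec <- rec <- f1 <- numeric(length(lev))
  for (i in seq_along(lev)) {
    tp <- cm[i, i]
    prec[i] <- if (sum(cm[, i]) == 0) 0 else tp / sum(cm[, i])
    rec[i] <- if (sum(cm[i, ]) == 0) 0 else tp / sum(cm[i, ])
    f1[i] <- if (prec[i] + rec[i] == 0) 0
             else 2 * prec[i] * rec[i] / (prec[i] + rec[i])
  }
  auc <- NA_real_
  if (!is.null(y_score)) {
    aucs <- vapply(seq_along(lev), function(i) {
      pos <- yt == lev[i]
      if (!any(pos) || all(pos)) return(NA_real_)
      binary_auc(y_score[, lev[i]], pos)
    }, numeric(1))
    auc <- if (length(lev) == 2) aucs[2] else mean(aucs, na.rm = TRUE)
  }
  list(accuracy = mean(yt == yp),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       auc = auc, confusion = cm)
}

# Rank-based AUC (equivalent to trapezoidal integration of the ROC curve).
binary_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier under stratified k-fold cross-validation
#'
#' @param config A [classifier_registry()] configuration.
#' @param features Data.frame or matrix of features.
#' @param labels Class labels.
#' @param plan A [cv_plan()].
#' @return An object of class `cv_result`: per-fold metric data.frame,
#'   mean and sd per metric, and the fold-aggregated confusion matrix.
#' @export
evaluate <- function(config, features, labels, plan = cv_plan()) {
  stopifnot(inherits(config, "classifier_config"))
  features <- as.data.frame(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  folds <- stratified_folds(labels, plan)
  per_fold <- vector("list", plan$k)
  cm_total <- NULL
  for (f in seq_len(plan$k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    if (length(unique(labels[train_idx])) < 2)
      stop("training folds degenerate to one class in fold ", f)
    pr <- fit_predict(config, features[train_idx, , drop = FALSE],
                      labels[train_idx],
                      features[test_idx, , drop = FALSE],
                      seed = plan$seed + f)
    m <- metric_suite(labels[test_idx], pr$predicted, pr$scores)
    cm_total <- if (is.null(cm_total)) m$confusion else cm_total + m$confusion
    per_fold[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                                precision = m$precision, recall = m$recall,
                                f1 = m$f1, auc = m$auc)
  }
  per_fold <- do.call(rbind, per_fold)
  metrics <- c("accuracy", "precision", "recall", "f1", "auc")
  structure(list(classifier = config$name,
                 per_fold = per_fold,
                 mean = vapply(per_fold[metrics], mean, numeric(1)),
                 sd = vapply(per_fold[metrics], stats::sd, numeric(1)),
                 confusion = cm_total,
                 plan = plan),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, stratified %d-fold (seed %d)\n",
              x$classifier, x$plan$k, x$plan$seed))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[m], x$sd[m]))
  cat("aggregated confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}

#' Three-class synthetic dataset
#'
#' Builds a labeled feature table over three generator profiles:
#' `resting` (artifacts only, no bursts), `five_finger` (gross
#' activation: 3--4 mV peaks, long 250--400 ms bursts) and
#' `individual_finger` (fine activation: 2--2.5 mV peaks, short
#' 150--250 ms bursts). Only windows matching the profile's activity
#' state (active for movement profiles, rest for resting) are kept, up to
#' `n_per_class` windows each.
#'
#' @param n_per_class Windows per class (default 50).
#' @param seed Master seed.
#' @param window_len Window length in samples.
#' @param zc_deadband_mv Zero-crossing dead-band (mV).
#' @return List with `features` (data.frame) and `labels` (factor).
#' @export
multiclass_dataset <- function(n_per_class = 50, seed = 1L,
                               window_len = 600, zc_deadband_mv = 0.1) {
  profiles <- list(
    resting = list(n_bursts = 0, amp = c(2, 4), dur = c(0.15, 0.4),
                   want_active = FALSE),
    five_finger = list(n_bursts = 24, amp = c(3, 4), dur = c(0.25, 0.4),
                       want_active = TRUE),
    individual_finger = list(n_bursts = 30, amp = c(2, 2.5),
                             dur = c(0.15, 0.25), want_active = TRUE))
  out_f <- list(); out_l <- character(0)
  for (pi in seq_along(profiles)) {
    p <- profiles[[pi]]
    got <- 0; chunk <- 0
    while (got < n_per_class && chunk < 20) {
      chunk <- chunk + 1
      cfg <- gen_config(duration_s = 30, n_bursts = p$n_bursts,
                        burst_amp_range_mv = p$amp,
                        burst_dur_range_s = p$dur,
                        seed = seed + 1000L * pi + chunk)
      tr <- synthesize(cfg)
      grid <- make_grid(length(tr$samples_mv), window_len, 0)
      truth <- truth_window_labels(tr, grid)
      keep <- which(truth == as.integer(p$want_active))
      if (length(keep) == 0) next
      w <- segment(tr, grid)[keep, , drop = FALSE]
      take <- min(nrow(w), n_per_class - got)
      out_f[[length(out_f) + 1]] <-
        feature_table(w[seq_len(take), , drop = FALSE],
                      zc_deadband_mv = zc_deadband_mv)
      out_l <- c(out_l, rep(names(profiles)[pi], take))
      got <- got + take
    }
    if (got < n_per_class)
      stop("could not assemble ", n_per_class, " windows for profile ",
           names(profiles)[pi])
  }
  list(features = do.call(rbind, out_f), labels = factor(out_l))
}
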