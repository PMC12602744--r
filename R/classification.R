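# Classifier families, confusion-matrix metrics, stratified cross-validation
# and ROC/AUC.
#
# Default hyperparameters are the ones reported for the study pipeline:
# SVM (RBF kernel, gamma 0.1, moderate penalty C = 1), gradient boosting
# (max depth 6, learning rate 0.1), decision tree (depth 8, <= 23 leaves,
# min split 2, entropy criterion), random forest (4 features per split,
# 40 trees), kNN (k = 10, Manhattan distance, inverse-distance weighting).

#' Classifier specification
#'
#' @param family One of `"svm"`, `"gboost"`, `"dtree"`, `"rforest"`, `"knn"`.
#' @param task `"binary"` or `"multiclass"`.
#' @param params Named list of hyperparameter overrides.
#' @param seed Integer seed governing all stochastic components of the fit.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "gboost", "dtree", "rforest", "knn"),
                            task = c("binary", "multiclass"),
                            params = list(), seed = 1L) {
  family <- match.arg(family)
  task <- match.arg(task)
  defaults <- switch(family,
    svm     = list(gamma = 0.1, cost = 1),
    gboost  = list(max_depth = 6, eta = 0.1, nrounds = 100),
    dtree   = list(maxdepth = 8, max_leaves = 23, minsplit = 2),
    rforest = list(mtry = 4, ntree = 40),
    knn     = list(k = 10, leaf_size = 20)
  )
  defaults[names(params)] <- params
  structure(list(family = family, task = task, params = defaults,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

model_matrix_from_table <- function(tbl) {
  fcols <- intersect(feature_names(), names(tbl))
  vm_check(length(fcols) >= 1L, "vm_parameter_error", "no feature columns found")
  x <- as.matrix(tbl[, fcols, drop = FALSE])
  if (anyNA(x)) {
    vm_stop("vm_parameter_error",
            "training/evaluation data contain missing values; run preprocess() first")
  }
  x
}

#' Fit a classifier on a feature table
#'
#' @param spec A [classifier_spec()].
#' @param train Feature table with a `class_label` column and no missing
#'   feature values.
#' @return A `fitted_model` usable with [predict_model()].
#' @export
fit_classifier <- function(spec, train) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- model_matrix_from_table(train)
  y <- train$class_label
  vm_check(!anyNA(y), "vm_parameter_error", "class_label has missing values")
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    vm_stop("vm_degenerate_training", "training set contains a single class")
  }
  yf <- factor(y, levels = classes)
  p <- spec$params
  fit <- with_local_seed(spec$seed, switch(spec$family,
    svm = e1071::svm(x, yf, kernel = "radial", gamma = p$gamma, cost = p$cost,
                     probability = TRUE, scale = FALSE),
    gboost = {
      obj <- if (length(classes) == 2L) "binary:logistic" else "multi:softprob"
      pars <- list(max_depth = p$max_depth, eta = p$eta, objective = obj,
                   nthread = 1)
      if (length(classes) > 2L) pars$num_class <- length(classes)
      xgboost::xgb.train(params = pars,
                         data = xgboost::xgb.DMatrix(x, label = as.integer(yf) - 1L),
                         nrounds = p$nrounds, verbose = 0)
    },
    dtree = {
      d <- data.frame(.y = yf, x, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = d, method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(
                            maxdepth = p$maxdepth, minsplit = p$minsplit,
                            cp = 0, xval = 0))
      prune_to_leaves(fit, p$max_leaves)
    },
    rforest = randomForest::randomForest(
      x, yf, mtry = min(p$mtry, ncol(x)), ntree = p$ntree),
    knn = list(x = x, y = yf, k = p$k)
  ))
  structure(list(spec = spec, fit = fit, classes = classes,
                 features = colnames(x)),
            class = "fitted_model")
}

# Prune an rpart tree until it has at most `max_leaves` terminal nodes,
# walking up its complexity path.
prune_to_leaves <- function(fit, max_leaves) {
  n_leaves <- function(f) sum(f$frame$var == "<leaf>")
  if (n_leaves(fit) <= max_leaves) return(fit)
  cps <- sort(unique(fit$cptable[, "CP"]))
  for (cp in cps) {
    fit2 <- rpart::prune(fit, cp = cp + 1e-12)
    if (n_leaves(fit2) <= max_leaves) return(fit2)
  }
  fit
}

#' Predict labels and class scores
#'
#' @param model A `fitted_model` from [fit_classifier()].
#' @param newdata Feature table (or matrix) of records to score.
#' @return List with `labels` (predicted class labels) and `scores`: a
#'   matrix of class probabilities (columns named by class), plus `score1` —
#'   the positive-class (label 1) score for binary ranking.
#' @export
predict_model <- function(model, newdata) {
  stopifnot(inherits(model, "fitted_model"))
  x <- if (is.matrix(newdata)) newdata else model_matrix_from_table(newdata)
  x <- x[, model$features, drop = FALSE]
  classes <- model$classes
  k <- length(classes)
  prob <- switch(model$spec$family,
    svm = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      pm <- attr(pr, "probabilities")
      pm[, as.character(classes), drop = FALSE]
    },
    gboost = {
      raw <- stats::predict(model$fit, x)
      if (k == 2L) cbind(1 - raw, raw) else matrix(raw, ncol = k, byrow = TRUE)
    },
    dtree = {
      d <- data.frame(x, check.names = FALSE)
      stats::predict(model$fit, d, type = "prob")
    },
    rforest = stats::predict(model$fit, x, type = "prob"),
    knn = knn_prob(model$fit, x)
  )
  prob <- as.matrix(prob)
  colnames(prob) <- as.character(classes)
  labels <- classes[max.col(prob, ties.method = "first")]
  list(labels = labels, scores = prob,
       score1 = if ("1" %in% colnames(prob)) prob[, "1"] else prob[, k])
}

# Brute-force kNN with Manhattan distance and inverse-distance weights.
knn_prob <- function(fit, x) {
  k <- min(fit$k, nrow(fit$x))
  classes <- levels(fit$y)
  out <- matrix(0, nrow = nrow(x), ncol = length(classes),
                dimnames = list(NULL, classes))
  for (i in seq_len(nrow(x))) {
    d <- rowSums(abs(sweep(fit$x, 2, x[i, ])))
    nn <- order(d)[seq_len(k)]
    w <- 1 / pmax(d[nn], 1e-12)
    for (ci in seq_along(classes)) {
      out[i, ci] <- sum(w[fit$y[nn] == classes[ci]])
    }
    out[i, ] <- out[i, ] / sum(out[i, ])
  }
  out
}

#' Confusion matrix from true and predicted labels
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param classes Optional class levels (default: sorted union).
#' @return A `confusion_matrix`: square count matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  m <- table(factor(truth, levels = classes),
             factor(predicted, levels = classes))
  structure(unclass(as.matrix(m)), class = "confusion_matrix")
}

#' Binary confusion matrix from the four counts
#'
#' Class 1 is the positive (pathological) class.
#'
#' @param TP,TN,FP,FN Non-negative counts.
#' @return A `confusion_matrix` with classes 0 and 1.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  vm_check(all(c(TP, TN, FP, FN) >= 0), "vm_parameter_error",
           "counts must be non-negative")
  m <- matrix(c(TN, FP, FN, TP), nrow = 2, byrow = TRUE,
              dimnames = list(c("0", "1"), c("0", "1")))
  structure(m, class = "confusion_matrix")
}

mcc_from_counts <- function(TP, TN, FP, FN) {
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)   # degenerate margin: defined as 0
  (TP * TN - FP * FN) / sqrt(den)
}

#' Performance metrics of a confusion matrix
#'
#' Binary metrics with class 1 positive:
#' `Acc = (TP+TN)/total`, `Sens = TP/(TP+FN)`, `Spec = TN/(TN+FP)`,
#' `Prec = TP/(TP+FP)`, `F1 = 2*Prec*Sens/(Prec+Sens)` (0 when the
#' denominator vanishes) and the Matthews correlation coefficient. For a
#' K-class matrix the metrics are unweighted (macro) one-vs-rest averages.
#' Values are also reported rounded half-up to 2 decimals for comparison
#' with published tables.
#'
#' @param cm A `confusion_matrix`.
#' @return List with `Acc`, `Sens`, `Spec`, `Prec`, `F1`, `MCC` and a
#'   `rounded` sub-list of 2-decimal versions.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  total <- sum(m)
  vm_check(total > 0, "vm_parameter_error", "empty confusion matrix")
  k <- nrow(m)
  one_vs_rest <- function(ci) {
    TP <- m[ci, ci]
    FN <- sum(m[ci, ]) - TP
    FP <- sum(m[, ci]) - TP
    TN <- total - TP - FN - FP
    sens <- if (TP + FN > 0) TP / (TP + FN) else 0
    spec <- if (TN + FP > 0) TN / (TN + FP) else 0
    prec <- if (TP + FP > 0) TP / (TP + FP) else 0
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    c(Acc = (TP + TN) / total, Sens = sens, Spec = spec, Prec = prec,
      F1 = f1, MCC = mcc_from_counts(TP, TN, FP, FN))
  }
  vals <- if (k == 2L) {
    v <- one_vs_rest(2L)        # class "1" (second level) is positive
    v["Acc"] <- sum(diag(m)) / total
    v
  } else {
    v <- rowMeans(vapply(seq_len(k), one_vs_rest, numeric(6)))
    v["Acc"] <- sum(diag(m)) / total
    v
  }
  out <- as.list(vals)
  out$rounded <- lapply(out, function(v) floor(v * 100 + 0.5) / 100)
  out
}

#' Stratified k-fold cross-validation
#'
#' Folds preserve per-class proportions to within one record. Metrics are
#' computed per fold and pooled (micro) over the concatenated out-of-fold
#' predictions; fold assignment is deterministic given the seed.
#'
#' @param spec A [classifier_spec()].
#' @param tbl Feature table (no missing feature values).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold shuffling.
#' @return List with `pooled` metrics, `pooled_cm`, `fold_metrics` (list),
#'   `fold_assignment`, and out-of-fold `scores`/`labels`.
#' @export
cross_validate <- function(spec, tbl, k = 10L, seed = 1L) {
  vm_check(k >= 2L, "vm_parameter_error", "k must be >= 2")
  y <- tbl$class_label
  counts <- table(y)
  if (any(counts < k)) {
    vm_stop("vm_stratification_error",
            sprintf("smallest class (%d rows) is below k = %d", min(counts), k))
  }
  n <- nrow(tbl)
  folds <- integer(n)
  with_local_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(y == as.integer(cl)))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  classes <- sort(unique(y))
  oof_labels <- rep(NA_integer_, n)
  oof_scores <- matrix(NA_real_, nrow = n, ncol = length(classes),
                       dimnames = list(NULL, as.character(classes)))
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- tbl[folds != f, , drop = FALSE]
    te <- tbl[folds == f, , drop = FALSE]
    model <- fit_classifier(spec, tr)
    pr <- predict_model(model, te)
    oof_labels[folds == f] <- pr$labels
    oof_scores[folds == f, ] <- pr$scores
    fold_metrics[[f]] <- compute_metrics(
      confusion_matrix(te$class_label, pr$labels, classes))
  }
  pooled_cm <- confusion_matrix(y, oof_labels, classes)
  list(pooled = compute_metrics(pooled_cm), pooled_cm = pooled_cm,
       fold_metrics = fold_metrics, fold_assignment = folds,
       labels = oof_labels, scores = oof_scores)
}

#' ROC curve by threshold sweep
#'
#' Predict positive when `score >= t`, sweeping `t` over the unique scores
#' (plus sentinels), yielding a staircase from (0,0) to (1,1). With constant
#' scores the curve is the chance diagonal (AUC 0.5).
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels True labels, positive class = 1 (or `TRUE`).
#' @return Data frame with `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(scores, labels) {
  pos <- labels == 1 | labels == TRUE
  vm_check(any(pos) && any(!pos), "vm_stratification_error",
           "ROC needs both classes present")
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(ths, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(fpr = fpr, tpr = tpr, threshold = ths)
}

#' Area under a ROC curve (trapezoidal rule)
#'
#' @param roc Data frame from [roc_points()].
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Cross-validated ROC/AUC
#'
#' Stratified k-fold (default 3, matching the reported evaluation); ROC
#' points and trapezoidal AUC per fold from out-of-fold scores; for
#' multiclass, macro one-vs-rest AUC per fold.
#'
#' @param spec A [classifier_spec()].
#' @param tbl Feature table.
#' @param k Number of folds (default 3).
#' @param seed Integer seed.
#' @return List with `fold_rocs` (binary only), `fold_auc`, `mean_auc`,
#'   `sd_auc`.
#' @export
roc_auc_cv <- function(spec, tbl, k = 3L, seed = 1L) {
  cv <- cross_validate(spec, tbl, k = k, seed = seed)
  y <- tbl$class_label
  classes <- sort(unique(y))
  folds <- cv$fold_assignment
  fold_auc <- numeric(k)
  fold_rocs <- vector("list", k)
  for (f in seq_len(k)) {
    sel <- folds == f
    if (length(classes) == 2L) {
      roc <- roc_points(cv$scores[sel, "1"], as.integer(y[sel] == classes[2]))
      fold_rocs[[f]] <- roc
      fold_auc[f] <- auc_trapezoid(roc)
    } else {
      aucs <- vapply(classes, function(cl) {
        auc_trapezoid(roc_points(cv$scores[sel, as.character(cl)],
                                 as.integer(y[sel] == cl)))
      }, numeric(1))
      fold_auc[f] <- mean(aucs)
    }
  }
  list(fold_rocs = fold_rocs, fold_auc = fold_auc,
       mean_auc = mean(fold_auc), sd_auc = stats::sd(fold_auc))
}

#' Exhaustive grid search by cross-validated accuracy
#'
#' Evaluates every combination in `grid` with [cross_validate()] and returns
#' the spec achieving the best mean fold accuracy.
#'
#' @param spec Base [classifier_spec()].
#' @param tbl Feature table.
#' @param grid Named list of parameter value vectors.
#' @param k CV folds.
#' @param seed Integer seed.
#' @return List with `best_spec`, `best_accuracy`, `results` data frame.
#' @export
grid_search <- function(spec, tbl, grid, k = 5L, seed = 1L) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  vm_check(nrow(combos) >= 1L, "vm_parameter_error", "empty grid")
  acc <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sp <- classifier_spec(spec$family, spec$task,
                          params = utils::modifyList(spec$params,
                                                     as.list(combos[i, , drop = FALSE])),
                          seed = spec$seed)
    acc[i] <- mean(vapply(cross_validate(sp, tbl, k = k, seed = seed)$fold_metrics,
                          function(m) m$Acc, numeric(1)))
  }
  best <- which.max(acc)
  best_spec <- classifier_spec(spec$family, spec$task,
                               params = utils::modifyList(spec$params,
                                                          as.list(combos[best, , drop = FALSE])),
                               seed = spec$seed)
  list(best_spec = best_spec, best_accuracy = acc[best],
       results = cbind(combos, accuracy = acc))
}
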