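test_that("the published SVM and XGBoost confusion matrices reproduce the table", {
  svm_cm <- confusion_counts(TP = 194, TN = 113, FP = 7, FN = 3)
  m <- compute_metrics(svm_cm)
  expect_equal(m$rounded$Acc, 0.97)
  expect_equal(m$rounded$Prec, 0.97)
  expect_equal(m$rounded$MCC, 0.93)
  xgb_cm <- confusion_counts(TP = 195, TN = 114, FP = 6, FN = 2)
  expect_equal(compute_metrics(xgb_cm)$rounded$MCC, 0.95)
})

test_that("perfect and inverted predictions hit the metric extremes", {
  perfect <- compute_metrics(confusion_counts(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_true(all(unlist(perfect[c("Acc", "Sens", "Spec", "Prec", "F1")]) == 1))
  expect_equal(perfect$MCC, 1)
  inverted <- compute_metrics(confusion_counts(TP = 0, TN = 0, FP = 50, FN = 50))
  expect_equal(inverted$MCC, -1)
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)),
               class = "vm_parameter_error")
})

test_that("metric identities hold against direct formulas on random matrices", {
  set.seed(19)
  for (i in 1:1000) {
    cnt <- sample(0:200, 4, replace = TRUE)
    if (sum(cnt) == 0) next
    TP <- cnt[1]; TN <- cnt[2]; FP <- cnt[3]; FN <- cnt[4]
    m <- compute_metrics(confusion_counts(TP, TN, FP, FN))
    o <- oracle_metrics(TP, TN, FP, FN)
    expect_equal(m$Acc, o$Acc, tolerance = 1e-12)
    if (is.finite(o$F1)) expect_equal(m$F1, o$F1, tolerance = 1e-12)
    if (is.finite(o$MCC)) {
      expect_equal(m$MCC, o$MCC, tolerance = 1e-12)
      expect_lte(abs(m$MCC), 1)
      # MCC invariant under simultaneous TP<->TN, FP<->FN swap
      expect_equal(compute_metrics(confusion_counts(TN, TP, FN, FP))$MCC,
                   m$MCC, tolerance = 1e-12)
    }
  }
})

test_that("MCC vanishes for matrices proportional to their margins", {
  # independence: counts = outer product of margins
  m <- compute_metrics(confusion_counts(TP = 30, TN = 20, FP = 45, FN = 40 / 3))
  expect_equal(m$MCC, 0, tolerance = 1e-12)
})

test_that("every classifier family separates the 3-sd synthetic table", {
  tbl <- separated_table(n = 100, seed = 42)
  sp <- stratified_split(tbl, 0.3, seed = 1)
  fit_rows <- seq_len(nrow(sp$train))
  scaled <- preprocess(rbind(sp$train, sp$test), fit_rows)
  train <- scaled[fit_rows, ]; test <- scaled[-fit_rows, ]
  for (fam in c("svm", "gboost", "dtree", "rforest", "knn")) {
    model <- fit_classifier(classifier_spec(fam, seed = 7), train)
    pred <- predict_model(model, test)
    acc <- mean(pred$labels == test$class_label)
    expect_gte(acc, 0.95)
    # determinism: same spec, same seed, same data
    pred2 <- predict_model(fit_classifier(classifier_spec(fam, seed = 7), train),
                           test)
    expect_identical(pred$labels, pred2$labels)
  }
})

test_that("degenerate training inputs are rejected", {
  tbl <- separated_table(n = 20, seed = 2)
  one_class <- tbl[tbl$class_label == 0, ]
  expect_error(fit_classifier(classifier_spec("svm"), one_class),
               class = "vm_degenerate_training")
  holed <- tbl; holed[[feature_names()[1]]][3] <- NA
  expect_error(fit_classifier(classifier_spec("svm"), holed),
               class = "vm_parameter_error")
})

test_that("the pruned decision tree respects its leaf budget", {
  tbl <- separated_table(n = 150, seed = 8)
  model <- fit_classifier(classifier_spec("dtree", seed = 1), tbl)
  expect_lte(sum(model$fit$frame$var == "<leaf>"), 23)
})

test_that("stratified cross-validation balances folds and pools counts", {
  tbl <- separated_table(n = 60, seed = 5)[c(1:60, 61:100), ]  # 60/40
  cv <- cross_validate(classifier_spec("dtree", seed = 2), tbl, k = 10, seed = 3)
  for (f in 1:10) {
    sel <- cv$fold_assignment == f
    expect_equal(sum(tbl$class_label[sel] == 0), 6)
    expect_equal(sum(tbl$class_label[sel] == 1), 4)
  }
  expect_equal(sum(cv$pooled_cm), nrow(tbl))
  expect_gte(cv$pooled$Acc, 0.9)   # separable data
  expect_error(cross_validate(classifier_spec("dtree"), tbl, k = 1),
               class = "vm_parameter_error")
  tiny <- tbl[c(1:30, 61:65), ]
  expect_error(cross_validate(classifier_spec("dtree"), tiny, k = 10),
               class = "vm_stratification_error")
})

test_that("ROC construction handles perfect, random and constant scores", {
  labels <- rep(c(0, 1), each = 100)
  roc <- roc_points(labels, labels)
  expect_equal(auc_trapezoid(roc), 1)
  set.seed(4)
  rnd <- stats::runif(2000)
  lab <- rep(c(0, 1), 1000)
  expect_lt(abs(auc_trapezoid(roc_points(rnd, lab)) - 0.5), 0.05)
  const <- roc_points(rep(0.7, 50), rep(c(0, 1), 25))
  expect_equal(auc_trapezoid(const), 0.5)
})

test_that("trapezoidal AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- stats::rnorm(300)
  labels <- as.integer(stats::runif(300) < stats::plogis(scores))
  ours <- auc_trapezoid(roc_points(scores, labels))
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("cross-validated AUC is near 1 on separable data", {
  tbl <- separated_table(n = 60, seed = 13)
  rc <- roc_auc_cv(classifier_spec("rforest", seed = 2), tbl, k = 3, seed = 5)
  expect_gte(rc$mean_auc, 0.98)
  expect_length(rc$fold_auc, 3)
})

test_that("multiclass metrics are macro one-vs-rest averages", {
  cm <- confusion_matrix(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 2, 0),
                         classes = 0:2)
  m <- compute_metrics(cm)
  expect_equal(m$Acc, 4 / 6, tolerance = 1e-12)
  # macro sensitivity: mean of per-class recalls 1/2, 1, 1/2... per matrix
  expect_equal(m$Sens, mean(c(1 / 2, 1, 1 / 2)), tolerance = 1e-12)
})
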