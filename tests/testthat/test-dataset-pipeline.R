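test_that("a full synthetic record populates all 28 features", {
  wf <- quick_vowel("a", seed = 4, f0 = 120, dur = 0.6, sr = 16000,
                    jitter_rel = 0.01, shimmer_rel = 0.03, hnr_db = 20)
  inv <- formant_inventory(a = c(730, 1090), e = c(530, 1840), i = c(270, 2290),
                           o = c(570, 840), u = c(300, 870))
  fv <- extract_record_features(wf, inv)
  expect_length(fv, 28)
  expect_identical(names(fv), feature_names())
  expect_equal(sum(!is.na(fv)), 28)
})

test_that("extractor failures degrade to missing fields, never abort", {
  # speech-only subject: no articulation features
  wf <- quick_vowel("a", seed = 4, f0 = 120, dur = 0.6, sr = 16000)
  fv <- extract_record_features(wf, NULL)
  expect_true(all(is.na(fv[c("TVSA", "QVSA", "FCR")])))
  expect_equal(sum(!is.na(fv)), 25)
  # white noise: cycle-based fields missing, frame-based ones present
  set.seed(11)
  nz <- waveform(stats::rnorm(16000) / 5, 16000)
  fvn <- extract_record_features(nz, NULL)
  expect_true(all(is.na(fvn[c("F0", "Jitter_rel", "Shim_rel", "HNR")])))
  expect_false(anyNA(fvn[c("ZCR_mean", "ZCR_median", "SC_mean", "SC_median")]))
})

test_that("consolidate walks subject folders deterministically", {
  root <- withr::local_tempdir()
  for (i in 1:3) {
    sp <- pulse_train_spec(f0 = 110 + 15 * i, duration = 0.4,
                           sample_rate = 16000, jitter_rel = 0.01,
                           shimmer_rel = 0.02, hnr_db = 20, seed = i)
    write_session(generate_session(sprintf("S%02d", i), (i - 1L) %% 2L, sp,
                                   seed = i), root)
  }
  tbl <- consolidate(root, csv_path = file.path(root, "f.csv"))
  expect_equal(nrow(tbl), 33)
  expect_identical(intersect(feature_names(), names(tbl)), feature_names())
  expect_true(all(c("record_id", "subject_id", "content", "class_label") %in%
                    names(tbl)))
  expect_equal(anyDuplicated(tbl$record_id), 0)
  csv1 <- readBin(file.path(root, "f.csv"), "raw",
                  file.size(file.path(root, "f.csv")))
  consolidate(root, csv_path = file.path(root, "f2.csv"))
  csv2 <- readBin(file.path(root, "f2.csv"), "raw",
                  file.size(file.path(root, "f2.csv")))
  expect_identical(csv1, csv2)
  # corrupt file: warning, remaining rows intact
  writeBin(as.raw(1:100), file.path(root, "S01", "u_9.wav"))
  expect_warning(tbl2 <- consolidate(root, csv_path = NA), "skipping")
  expect_equal(nrow(tbl2), 33)
  expect_error(consolidate(withr::local_tempdir()), class = "vm_empty_dataset")
})

test_that("preprocess imputes then standardizes on the fitting rows only", {
  tbl <- separated_table(n = 30, seed = 3)
  col <- feature_names()[1]
  tbl[[col]][1:3] <- c(1, 2, 3)
  tbl[[col]][4] <- NA
  out <- preprocess(tbl, fit_rows = 1:3)
  # closed-form z-scores of (1,2,3) with population sd
  expect_equal(out[[col]][1:3], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  # the missing cell was imputed to the fitting mean (2) before scaling -> 0
  expect_equal(out[[col]][4], 0)
  # fitted columns have mean 0, population sd 1 on fitting rows
  for (cc in feature_names()[1:5]) {
    v <- out[[cc]][1:3]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  }
})

test_that("preprocess is idempotent and guards degenerate columns", {
  tbl <- separated_table(n = 20, seed = 9)
  fit <- 1:25
  once <- preprocess(tbl, fit)
  twice <- preprocess(once, fit)
  expect_equal(as.matrix(twice[, feature_names()]),
               as.matrix(once[, feature_names()]), tolerance = 1e-9)
  # test rows (outside fit) are not centered in general -> no leakage
  test_means <- colMeans(as.matrix(once[-fit, feature_names()]))
  expect_gt(max(abs(test_means)), 0.1)
  const <- tbl; const[[feature_names()[2]]] <- 5
  expect_warning(preprocess(const), "zero-variance")
  allna <- tbl; allna[[feature_names()[3]]] <- NA_real_
  expect_error(preprocess(allna), class = "vm_degenerate_column")
})

test_that("augmentation balances classes with bounded stretch factors", {
  recs <- c(
    lapply(1:6, function(i) {
      w <- quick_train(seed = i, dur = 0.3, sr = 8000); w$class_label <- 0L; w
    }),
    lapply(7:9, function(i) {
      w <- quick_train(seed = i, dur = 0.3, sr = 8000); w$class_label <- 1L; w
    })
  )
  out <- augment_minority(recs, seed = 5)
  labels <- vapply(out, function(w) w$class_label, integer(1))
  expect_equal(sum(labels == 0), 6)
  expect_equal(sum(labels == 1), 6)
  augd <- out[vapply(out, function(w) isTRUE(attr(w, "augmented")), logical(1))]
  expect_length(augd, 3)
  for (a in augd) {
    ratio <- length(a$samples) / length(recs[[7]]$samples)
    expect_true(ratio > 0.985 && ratio < 1.015)
  }
  expect_identical(
    lapply(augment_minority(recs, seed = 5), function(w) w$samples),
    lapply(out, function(w) w$samples))
  expect_error(augment_minority(recs, factor_range = c(0.5, 1.5)),
               class = "vm_parameter_error")
})

test_that("stratified split reproduces the published record counts", {
  mk <- function(n0, n1) data.frame(
    record_id = seq_len(n0 + n1), subject_id = "s", content = "a",
    class_label = rep(c(0L, 1L), c(n0, n1)), augmented = FALSE)
  s1 <- stratified_split(mk(660, 396), 0.30, seed = 1)
  expect_equal(nrow(s1$test), 317)
  expect_equal(nrow(s1$train), 739)
  s2 <- stratified_split(mk(340, 330), 0.20, seed = 1)
  expect_equal(nrow(s2$test), 134)
  expect_equal(nrow(s2$train), 536)
  expect_error(stratified_split(mk(10, 10), 0), class = "vm_parameter_error")
})

test_that("splits partition the rows and preserve class proportions", {
  set.seed(31)
  for (i in 1:50) {
    n0 <- sample(10:80, 1); n1 <- sample(10:80, 1)
    frac <- runif(1, 0.1, 0.5)
    tbl <- data.frame(record_id = seq_len(n0 + n1), subject_id = "s",
                      content = "a",
                      class_label = sample(rep(c(0L, 1L), c(n0, n1))),
                      augmented = FALSE)
    sp <- stratified_split(tbl, frac, seed = i)
    expect_equal(sort(c(sp$train$record_id, sp$test$record_id)),
                 tbl$record_id)
    expect_length(intersect(sp$train$record_id, sp$test$record_id), 0)
    n_test <- floor(frac * nrow(tbl) + 0.5)
    expect_equal(nrow(sp$test), n_test)
    for (cl in 0:1) {
      expected <- n_test * sum(tbl$class_label == cl) / nrow(tbl)
      expect_lte(abs(sum(sp$test$class_label == cl) - expected), 1)
    }
  }
})

test_that("augmented rows never land in the test part", {
  tbl <- data.frame(record_id = 1:40, subject_id = "s", content = "a",
                    class_label = rep(c(0L, 1L), each = 20),
                    augmented = rep(c(FALSE, TRUE), 20))
  sp <- stratified_split(tbl, 0.25, seed = 2)
  expect_false(any(sp$test$augmented))
})
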