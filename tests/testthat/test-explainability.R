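# Toy value functions use marginal masking over an explicit background, so
# exact axioms can be checked against closed forms.

linear_vf <- function(beta, background) {
  vf_marginal(function(x) as.numeric(x %*% beta), background)
}

test_that("additive model splits attributions by feature contribution", {
  bg <- matrix(stats::rnorm(400), ncol = 2)
  bg <- sweep(bg, 2, colMeans(bg))          # zero-mean background
  vf <- linear_vf(c(1, 1), bg)
  ex <- shapley_exact(vf, c(x1 = 2, x2 = -1))
  expect_equal(unname(ex$phi), c(2, -1), tolerance = 1e-9)
  expect_equal(sum(ex$phi), ex$fx - ex$baseline, tolerance = 1e-9)
})

test_that("dummy and symmetry axioms hold exactly in enumeration mode", {
  set.seed(23)
  bg <- matrix(stats::rnorm(300), ncol = 3)
  # model ignores feature 3
  vf <- vf_marginal(function(x) x[, 1] * x[, 2], bg)
  ex <- shapley_exact(vf, c(a = 1.5, b = -0.5, c = 99))
  expect_equal(unname(ex$phi[3]), 0, tolerance = 1e-9)
  # symmetric model, equal instance values
  bg_s <- cbind(bg[, 1], bg[, 1], bg[, 3])  # exchangeable background
  vf_s <- vf_marginal(function(x) x[, 1] + x[, 2] + 0.5 * x[, 1] * x[, 2], bg_s)
  ex_s <- shapley_exact(vf_s, c(a = 0.7, b = 0.7, c = 0.1))
  expect_equal(unname(ex_s$phi[1]), unname(ex_s$phi[2]), tolerance = 1e-9)
})

test_that("efficiency, symmetry and dummy hold over random toy models", {
  set.seed(29)
  for (i in 1:50) {
    m <- sample(3:7, 1)
    bg <- matrix(stats::rnorm(40 * m), ncol = m)
    beta <- stats::rnorm(m)
    inter <- stats::rnorm(1)
    f <- function(x) as.numeric(x %*% beta) + inter * x[, 1] * x[, 2]
    vf <- vf_marginal(f, bg)
    inst <- stats::rnorm(m)
    ex <- shapley_exact(vf, inst)
    expect_equal(sum(ex$phi), ex$fx - ex$baseline, tolerance = 1e-9)
  }
})

test_that("linearity: attributions of a sum are sums of attributions", {
  set.seed(31)
  m <- 5
  bg <- matrix(stats::rnorm(50 * m), ncol = m)
  b1 <- stats::rnorm(m); b2 <- stats::rnorm(m)
  inst <- stats::rnorm(m)
  g <- shapley_exact(linear_vf(b1, bg), inst)
  h <- shapley_exact(linear_vf(b2, bg), inst)
  gh <- shapley_exact(linear_vf(b1 + b2, bg), inst)
  expect_equal(unname(gh$phi), unname(g$phi + h$phi), tolerance = 1e-9)
})

test_that("retraining value function realizes the subset-model game", {
  set.seed(37)
  n <- 80
  x <- matrix(stats::rnorm(n * 3), ncol = 3)
  # center and orthogonalize so subset refits decouple across features
  x <- qr.Q(qr(scale(x, scale = FALSE))) * sqrt(n)
  y <- 2 * x[, 1] - x[, 2] + stats::rnorm(n, 0, 0.01)
  vf <- vf_retrain(
    fit_fun = function(xs, ys) stats::lm.fit(cbind(1, xs), ys),
    pred_fun = function(fit, xs) sum(c(1, xs[1, ]) * fit$coefficients),
    x = x, y = y)
  ex <- shapley_exact(vf, c(1, 1, 1))
  expect_equal(sum(ex$phi), ex$fx - ex$baseline, tolerance = 1e-6)
  expect_lt(abs(ex$phi[3]), 0.05)       # near-dummy feature
  expect_gt(ex$phi[1], ex$phi[2])       # stronger positive contributor
})

test_that("sampled estimates agree with enumeration within 3 standard errors", {
  set.seed(41)
  m <- 8
  bg <- matrix(stats::rnorm(60 * m), ncol = m)
  beta <- stats::rnorm(m)
  vf <- vf_marginal(function(x) as.numeric(x %*% beta) + 0.3 * x[, 1] * x[, 3],
                    bg)
  inst <- stats::rnorm(m)
  exact <- shapley_exact(vf, inst)
  samp <- shapley_sampled(vf, inst, n_permutations = 2000, seed = 6)
  expect_true(all(abs(samp$phi - exact$phi) <= 3 * pmax(samp$se, 1e-8)))
  samp2 <- shapley_sampled(vf, inst, n_permutations = 2000, seed = 6)
  expect_identical(samp$phi, samp2$phi)
  expect_error(shapley_sampled(vf, inst, n_permutations = 1),
               class = "vm_parameter_error")
})

test_that("sampling error shrinks as permutations grow", {
  set.seed(43)
  m <- 6
  bg <- matrix(stats::rnorm(40 * m), ncol = m)
  beta <- stats::rnorm(m)
  vf <- vf_marginal(function(x) as.numeric(x %*% beta) + x[, 2] * x[, 4], bg)
  inst <- stats::rnorm(m)
  exact <- shapley_exact(vf, inst)
  err <- sapply(c(100, 1000, 10000), function(np) {
    mean(abs(shapley_sampled(vf, inst, n_permutations = np, seed = 2)$phi -
               exact$phi))
  })
  expect_lt(err[3], err[1])
})

test_that("large feature universes are routed to the sampler", {
  bg <- matrix(stats::rnorm(20 * 13), ncol = 13)
  vf <- vf_marginal(function(x) rowSums(x), bg)
  expect_error(shapley_exact(vf, numeric(13)), class = "vm_size_error")
})

test_that("global summary ranks dominant and designed signal features first", {
  mk_expl <- function(phi) structure(
    list(baseline = 0, phi = phi, fx = sum(phi),
         features = names(phi), mode = "marginal"),
    class = "shapley_explanation")
  phis <- lapply(1:10, function(i) {
    stats::setNames(c(1, stats::rnorm(3, 0, 0.05)), c("A", "B", "C", "D"))
  })
  rank <- summarize_global(lapply(phis, mk_expl))
  expect_equal(rank$feature[1], "A")
  # single explanation: ranking is its |phi| sort
  one <- summarize_global(list(mk_expl(c(A = 0.1, B = -2, C = 0.5))))
  expect_equal(one$feature, c("B", "C", "A"))
  bad <- list(mk_expl(c(A = 1, B = 2)), mk_expl(c(X = 1, Y = 2)))
  expect_error(summarize_global(bad), class = "vm_parameter_error")
})

test_that("class-discriminating features claim the top global ranks", {
  tbl <- generate_feature_table(feature_table_spec(
    n_per_class = c("0" = 60, "1" = 60),
    class_means = list(rep(0, 28),
                       replace(rep(0, 28), c(21, 22), 4)),  # MFCC mean/median
    class_sds = 1, seed = 17))
  scaled <- preprocess(tbl)
  model <- fit_classifier(classifier_spec("gboost", seed = 3), scaled)
  vf <- vf_model(model, scaled, max_background = 40, seed = 3)
  x <- as.matrix(scaled[, feature_names()])
  set.seed(3)
  idx <- sample(nrow(x), 12)
  expls <- lapply(idx, function(i) {
    shapley_sampled(vf, x[i, ], features = feature_names(),
                    n_permutations = 30, seed = i)
  })
  rank <- summarize_global(expls)
  expect_setequal(rank$feature[1:2], c("MFCC_mean", "MFCC_median"))
})

test_that("force records orient by threshold with ties pathological", {
  ex <- structure(list(baseline = 1.0, phi = c(a = -2, b = 0.5), fx = -0.5,
                       features = c("a", "b"), mode = "marginal"),
                  class = "shapley_explanation")
  fr <- force_record(ex)
  expect_equal(fr$orientation, "healthy")
  expect_equal(fr$contributors$feature[1], "a")
  ex$fx <- 1.0
  expect_equal(force_record(ex)$orientation, "pathological")
  ex0 <- structure(list(baseline = 0.3, phi = c(a = 0, b = 0), fx = 0.3,
                        features = c("a", "b"), mode = "marginal"),
                   class = "shapley_explanation")
  fr0 <- force_record(ex0)
  expect_equal(nrow(fr0$contributors), 0)
  expect_equal(fr0$orientation, "pathological")
})
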