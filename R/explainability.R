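# Shapley-value attribution.
#
# phi_i = sum over S subseteq F\{i} of |S|!(|F|-|S|-1)!/|F|! *
#         [v(S u {i}) - v(S)]
#
# Two value-function modes realize v:
#  * retraining — v(S) is the output of a model retrained on the features in
#    S (the literal game definition; exponential cost, used on <= 12
#    features);
#  * marginal masking — v(S) is the expected model output with the features
#    outside S integrated out over a background sample (the practical
#    default for 28 features).
# In both modes v(empty set) equals the baseline (mean training prediction),
# so the efficiency axiom reads sum(phi) = f(x) - baseline.

#' Marginal-expectation value function
#'
#' `v(S) = mean_b f(x_S, b_notS)` over the rows of a background sample;
#' `v(empty)` is the mean background prediction (the baseline).
#'
#' @param predict_fun Function mapping a numeric matrix of instances to a
#'   numeric vector of model outputs (use the margin/score, not the class).
#' @param background Numeric matrix (rows = background instances) whose
#'   columns are the feature universe.
#' @return A `value_function`.
#' @export
vf_marginal <- function(predict_fun, background) {
  background <- as.matrix(background)
  vm_check(nrow(background) >= 1L, "vm_parameter_error",
           "background sample is empty")
  baseline <- mean(predict_fun(background))
  v <- function(S, x) {
    if (length(S) == 0L) return(baseline)
    masked <- background
    masked[, S] <- matrix(x[S], nrow = nrow(background), ncol = length(S),
                          byrow = TRUE)
    mean(predict_fun(masked))
  }
  structure(list(v = v, baseline = baseline,
                 n_features = ncol(background), mode = "marginal"),
            class = "value_function")
}

#' Retraining value function
#'
#' `v(S)` retrains the model on the feature subset `S` and evaluates the
#' instance restricted to `S`; `v(empty)` is the mean training response.
#' Subset models are cached, so exact enumeration costs one fit per subset.
#'
#' @param fit_fun Function `(x_subset_matrix, y)` returning a fitted object.
#' @param pred_fun Function `(fit, x_subset_row_matrix)` returning a scalar
#'   model output.
#' @param x Training feature matrix.
#' @param y Training response (numeric).
#' @return A `value_function`.
#' @export
vf_retrain <- function(fit_fun, pred_fun, x, y) {
  x <- as.matrix(x)
  baseline <- mean(y)
  cache <- new.env(parent = emptyenv())
  v <- function(S, inst) {
    if (length(S) == 0L) return(baseline)
    S <- sort(S)
    key <- paste(S, collapse = ",")
    fit <- if (!is.null(cache[[key]])) cache[[key]] else {
      f <- fit_fun(x[, S, drop = FALSE], y)
      cache[[key]] <- f
      f
    }
    pred_fun(fit, matrix(inst[S], nrow = 1))
  }
  structure(list(v = v, baseline = baseline, n_features = ncol(x),
                 mode = "retrain"),
            class = "value_function")
}

shapley_weights <- function(m) {
  # weight for |S| = s: s!(m-s-1)!/m!
  s <- 0:(m - 1L)
  exp(lfactorial(s) + lfactorial(m - s - 1L) - lfactorial(m))
}

#' Exact Shapley values by subset enumeration
#'
#' Enumerates all `2^|F|` feature subsets and applies the combinatorial
#' weights exactly; the efficiency identity `sum(phi) = f(x) - baseline`
#' holds to numerical precision.
#'
#' @param vf A `value_function` ([vf_marginal()] or [vf_retrain()]).
#' @param instance Numeric vector over the feature universe.
#' @param features Optional feature names (defaults to `names(instance)`).
#' @return A `shapley_explanation`: list with `baseline`, `phi`, `fx`,
#'   `features`, `mode`.
#' @export
shapley_exact <- function(vf, instance, features = names(instance)) {
  stopifnot(inherits(vf, "value_function"))
  m <- length(instance)
  vm_check(m == vf$n_features, "vm_parameter_error",
           "instance length must match the value function's feature universe")
  if (m > 12L) {
    vm_stop("vm_size_error",
            sprintf("%d features need 2^%d evaluations; use shapley_sampled()", m, m))
  }
  if (is.null(features)) features <- paste0("x", seq_len(m))
  n_sub <- bitwShiftL(1L, m)
  vals <- numeric(n_sub)
  for (mask in 0:(n_sub - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    vals[mask + 1L] <- vf$v(S, instance)
  }
  w <- shapley_weights(m)
  phi <- numeric(m)
  for (i in seq_len(m)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(n_sub - 1L)) {
      if (bitwAnd(mask, bit) != 0L) next
      s_size <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
      phi[i] <- phi[i] + w[s_size + 1L] *
        (vals[bitwOr(mask, bit) + 1L] - vals[mask + 1L])
    }
  }
  structure(list(baseline = vf$baseline, phi = stats::setNames(phi, features),
                 fx = vals[n_sub], features = features, mode = vf$mode),
            class = "shapley_explanation")
}

#' Sampled Shapley values by permutation sampling
#'
#' Averages sequential marginal contributions over random feature
#' permutations; deterministic per seed, with per-feature standard errors.
#'
#' @param vf A `value_function`.
#' @param instance Numeric vector over the feature universe.
#' @param features Optional feature names.
#' @param n_permutations Number of permutations (`>= 10`).
#' @param seed Integer seed.
#' @return A `shapley_explanation` with an extra `se` field.
#' @export
shapley_sampled <- function(vf, instance, features = names(instance),
                            n_permutations = 200L, seed = 1L) {
  stopifnot(inherits(vf, "value_function"))
  m <- length(instance)
  vm_check(m == vf$n_features, "vm_parameter_error",
           "instance length must match the value function's feature universe")
  vm_check(n_permutations >= 10L, "vm_parameter_error",
           "n_permutations must be >= 10")
  if (is.null(features)) features <- paste0("x", seq_len(m))
  contrib <- matrix(0, nrow = n_permutations, ncol = m)
  with_local_seed(seed, {
    for (p in seq_len(n_permutations)) {
      perm <- sample.int(m)
      prev <- vf$v(integer(0), instance)
      S <- integer(0)
      for (i in perm) {
        S <- c(S, i)
        cur <- vf$v(S, instance)
        contrib[p, i] <- cur - prev
        prev <- cur
      }
    }
  })
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  structure(list(baseline = vf$baseline, phi = stats::setNames(phi, features),
                 fx = vf$v(seq_len(m), instance), features = features,
                 se = stats::setNames(se, features), mode = vf$mode),
            class = "shapley_explanation")
}

#' @export
print.shapley_explanation <- function(x, ...) {
  cat(sprintf("<shapley_explanation> baseline %.4f, f(x) %.4f, sum(phi) %.4f\n",
              x$baseline, x$fx, sum(x$phi)))
  ord <- order(abs(x$phi), decreasing = TRUE)
  top <- utils::head(ord, 5)
  for (i in top) cat(sprintf("  %-14s %+0.4f\n", x$features[i], x$phi[i]))
  invisible(x)
}

#' Global feature ranking from a set of explanations
#'
#' Features ranked by mean absolute attribution, the ordering used by
#' summary ("beeswarm") plots; the per-feature signed values are retained.
#'
#' @param explanations List of `shapley_explanation`s over the same
#'   feature universe.
#' @return Data frame with `feature`, `mean_abs_phi`, `rank`, and the signed
#'   value matrix as attribute `values`.
#' @export
summarize_global <- function(explanations) {
  vm_check(length(explanations) >= 1L, "vm_parameter_error",
           "need at least one explanation")
  feats <- explanations[[1]]$features
  for (e in explanations) {
    vm_check(identical(e$features, feats), "vm_parameter_error",
             "explanations use inconsistent feature universes")
  }
  vals <- do.call(rbind, lapply(explanations, function(e) e$phi))
  mean_abs <- colMeans(abs(vals))
  ord <- order(mean_abs, decreasing = TRUE)
  out <- data.frame(feature = feats[ord], mean_abs_phi = mean_abs[ord],
                    rank = seq_along(feats), row.names = NULL)
  attr(out, "values") <- vals
  out
}

#' Local force-style report for one explanation
#'
#' The instance is oriented healthy when `f(x)` falls below the threshold
#' (default: the baseline) and pathological otherwise (ties count as
#' pathological). Contributors are listed by decreasing `|phi|` with signs.
#'
#' @param expl A `shapley_explanation`.
#' @param threshold Decision threshold on the model output (default
#'   `expl$baseline`).
#' @param top Number of contributors to list.
#' @return List with `orientation` (`"healthy"`/`"pathological"`), `fx`,
#'   `baseline`, and a `contributors` data frame.
#' @export
force_record <- function(expl, threshold = expl$baseline, top = 10L) {
  stopifnot(inherits(expl, "shapley_explanation"))
  ord <- order(abs(expl$phi), decreasing = TRUE)
  nz <- ord[abs(expl$phi[ord]) > 0]
  sel <- utils::head(nz, top)
  list(
    orientation = if (expl$fx < threshold) "healthy" else "pathological",
    fx = expl$fx, baseline = expl$baseline, threshold = threshold,
    contributors = data.frame(feature = expl$features[sel],
                              phi = unname(expl$phi[sel]), row.names = NULL)
  )
}

#' Build a marginal value function for a fitted classifier
#'
#' Wires [vf_marginal()] to a `fitted_model`, explaining the positive-class
#' margin `log(p1 / (1 - p1))` (the pre-threshold score, which is what local
#' force reports display).
#'
#' @param model A `fitted_model` from [fit_classifier()].
#' @param background Feature matrix or table of background (training) rows;
#'   subsampled to `max_background` rows for tractability.
#' @param max_background Cap on background rows (default 100).
#' @param seed Seed for the subsample.
#' @return A `value_function`.
#' @export
vf_model <- function(model, background, max_background = 100L, seed = 1L) {
  bg <- if (is.matrix(background)) background else model_matrix_from_table(background)
  bg <- bg[, model$features, drop = FALSE]
  if (nrow(bg) > max_background) {
    with_local_seed(seed, {
      bg <- bg[sample.int(nrow(bg), max_background), , drop = FALSE]
    })
  }
  predict_fun <- function(x) {
    p1 <- predict_model(model, x)$score1
    p1 <- pmin(pmax(p1, 1e-6), 1 - 1e-6)
    log(p1 / (1 - p1))
  }
  vf_marginal(predict_fun, bg)
}
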