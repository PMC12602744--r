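# Acoustic perturbation metrics: five jitter measures, six shimmer measures,
# and the harmonic-to-noise ratio.
#
# The jitter/shimmer formulas follow the source publication's printed
# normalizations exactly (periods are 1-based T_1..T_N in the comments
# below; R vectors are 1-based so the mapping is direct):
#   Ja   = (1/N)   * sum_{i=2..N} |T_i - T_{i-1}|        (N-1 summands, 1/N)
#   Jr   = Ja / ((1/N) * sum_{i=1..N-1} T_i)             (first N-1 periods)
#   RAP  = [(1/(N-2)) * sum_{i=2..N-1} |mean(T_{i-1..i+1}) - T_i|] / same denom
#   PPQ5 = [(1/(N-4)) * sum_{i=3..N-2} |mean(T_{i-2..i+2}) - T_i|] / same denom
#   DDP  = (1/(N-1)) * sum_{i=2..N} |T_i - T_{i-1}|
# A `classical` switch replaces these with the textbook MDVP-style versions
# (all means over the full series, DDP = difference of consecutive diffs).

#' Jitter metrics of a cycle series
#'
#' @param cycles A [cycle_series()] (needs `N >= 5`; `N >= 3` suffices when
#'   `require_all = FALSE`, in which case PPQ5 is returned as `NA`).
#' @param classical Use textbook MDVP-style normalizations instead of the
#'   printed ones (default `FALSE`).
#' @param require_all Error when a metric's cycle-count precondition fails
#'   (default). With `FALSE`, that metric is `NA` and the rest are returned.
#' @return List with `Ja` (s), `Jr`, `RAP`, `PPQ5` (dimensionless), `DDP` (s).
#' @export
jitter_metrics <- function(cycles, classical = FALSE, require_all = TRUE) {
  stopifnot(inherits(cycles, "cycle_series"))
  T <- cycles$periods
  N <- length(T)
  if (N < 3L) vm_stop("vm_insufficient_cycles", "RAP requires N >= 3 cycles")
  if (N < 5L && require_all) {
    vm_stop("vm_insufficient_cycles",
            sprintf("PPQ5 requires N >= 5 cycles, got %d", N))
  }
  adiff <- abs(diff(T))
  denom <- if (classical) mean(T) else sum(T[1:(N - 1L)]) / N
  Ja <- if (classical) mean(adiff) else sum(adiff) / N
  Jr <- Ja / denom
  rap_num <- vapply(2:(N - 1L), function(i) {
    abs(mean(T[(i - 1L):(i + 1L)]) - T[i])
  }, numeric(1))
  RAP <- (sum(rap_num) / (N - 2L)) / denom
  PPQ5 <- NA_real_
  if (N >= 5L) {
    ppq_num <- vapply(3:(N - 2L), function(i) {
      abs(mean(T[(i - 2L):(i + 2L)]) - T[i])
    }, numeric(1))
    PPQ5 <- (sum(ppq_num) / (N - 4L)) / denom
  }
  DDP <- if (classical) {
    d <- diff(T); if (length(d) >= 2L) mean(abs(diff(d))) else 0
  } else {
    sum(adiff) / (N - 1L)
  }
  list(Ja = Ja, Jr = Jr, RAP = RAP, PPQ5 = PPQ5, DDP = DDP)
}

#' Shimmer metrics of a cycle series
#'
#' `Sr` and `SdB` follow the printed formulas (`SdB` without the absolute
#' value; it telescopes, which the `classical` switch undoes). `APQ_n` is the
#' mean absolute difference between each amplitude and the mean of its
#' `n - 1` neighboring cycles (`k` in `[-n/2, n/2]` excluding 0), edge cycles
#' skipped, divided by the mean amplitude. `DDA` is the mean absolute
#' consecutive amplitude difference.
#'
#' @param cycles A [cycle_series()].
#' @param classical Use `|20 log10|` terms in `SdB` (default `FALSE`).
#' @param require_all Error when a metric's cycle-count precondition fails;
#'   with `FALSE` (pipeline mode), under-supported APQ orders are `NA`.
#' @return List with `Sr`, `SdB` (dB), `APQ3`, `APQ5`, `APQ11`, `DDA`.
#' @export
shimmer_metrics <- function(cycles, classical = FALSE, require_all = TRUE) {
  stopifnot(inherits(cycles, "cycle_series"))
  A <- cycles$amplitudes
  N <- length(A)
  if (N < 2L) vm_stop("vm_insufficient_cycles", "shimmer requires N >= 2 cycles")
  adiff <- abs(diff(A))
  denom <- sum(A[1:(N - 1L)]) / N
  Sr <- (sum(adiff) / (N - 1L)) / denom
  SdB <- if (all(A > 0)) {
    ratio_terms <- 20 * log10(A[2:N] / A[1:(N - 1L)])
    if (classical) mean(abs(ratio_terms)) else mean(ratio_terms)
  } else NA_real_   # zero amplitudes have no dB ratio
  apq <- function(n) {
    h <- n %/% 2L
    min_n <- 2L * h + 2L   # at least one interior cycle plus both margins
    if (N < min_n) {
      if (require_all) {
        vm_stop("vm_insufficient_cycles",
                sprintf("APQ%d requires N >= %d cycles, got %d", n, min_n, N))
      }
      return(NA_real_)
    }
    ks <- setdiff(-h:h, 0L)
    idx <- (h + 1L):(N - h)
    num <- vapply(idx, function(i) abs(A[i] - mean(A[i + ks])), numeric(1))
    mean(num) / mean(A)
  }
  list(Sr = Sr, SdB = SdB, APQ3 = apq(3L), APQ5 = apq(5L), APQ11 = apq(11L),
       DDA = mean(adiff))
}

#' Harmonic-to-noise ratio of a voiced waveform
#'
#' Cycle-synchronous comb averaging: cycles (segmented at the detected cycle
#' landmarks, resampled to the median cycle length) are averaged to form the
#' harmonic template; the per-cycle residual is the noise estimate. Small-
#' sample bias of the template (`P_template = P_h + P_n / M` over `M` cycles)
#' is corrected. The value is `10 log10(harmonic power / noise power)`,
#' clipped to `[-20, 40]` dB — the standard HNR orientation (the printed
#' ratio in the source formula is inverted; that discrepancy is documented,
#' not silently adopted).
#'
#' @param wf A [waveform].
#' @param cycles Optional [cycle_series()] with landmark `onsets`; estimated
#'   from `wf` when missing.
#' @param f0_min,f0_max Pitch range for cycle estimation.
#' @return HNR in dB, clipped to `[-20, 40]`.
#' @export
harmonic_noise_ratio <- function(wf, cycles = NULL, f0_min = 60, f0_max = 500) {
  stopifnot(inherits(wf, "waveform"))
  if (is.null(cycles)) cycles <- estimate_cycles(wf, f0_min, f0_max)
  onsets <- cycles$onsets
  if (is.null(onsets) && !is.null(cycles$runs) && length(cycles$runs) > 0L) {
    # several voiced runs (speech item): use the longest one
    onsets <- cycles$runs[[which.max(lengths(cycles$runs))]]
  }
  if (is.null(onsets)) {
    vm_stop("vm_insufficient_voicing", "cycle landmarks unavailable")
  }
  if (length(onsets) < 6L) {
    vm_stop("vm_insufficient_voicing", "need at least 5 cycles for HNR")
  }
  sr <- wf$sample_rate
  x <- wf$samples
  on_smp <- onsets * sr
  M <- length(on_smp) - 1L
  L <- max(4L, round(stats::median(diff(on_smp))))
  mat <- matrix(NA_real_, nrow = M, ncol = L)
  attn_sum <- 0
  for (i in seq_len(M)) {
    lo <- on_smp[i]; hi <- on_smp[i + 1L]
    pos <- lo + (hi - lo) * (seq_len(L) - 1L) / L
    pos <- pmin(pmax(pos, 1), length(x))
    mat[i, ] <- stats::approx(seq_along(x), x, xout = pos, rule = 2)$y
    frac <- pos - floor(pos)
    attn_sum <- attn_sum + mean((1 - frac)^2 + frac^2)
  }
  # linear interpolation at fractional positions attenuates white-noise
  # power by (1-f)^2 + f^2; undo that so the noise estimate is on the
  # raw-signal scale
  attn <- attn_sum / M
  template <- colMeans(mat)
  resid <- sweep(mat, 2, template)
  p_res <- mean(resid^2)
  p_noise <- if (M > 1L) p_res * M / ((M - 1L) * attn) else p_res / attn
  p_harm <- mean(template^2) - attn * p_noise / M
  if (p_noise <= 0 || p_harm <= 0) {
    hnr <- if (p_noise <= 0) 40 else -20
  } else {
    hnr <- 10 * log10(p_harm / p_noise)
  }
  min(40, max(-20, hnr))
}

#' All 17 acoustic-domain features of a recording
#'
#' F0 and F1–F4 from the cycle/formant estimators, the five jitter and six
#' shimmer metrics, and HNR. In pipeline mode individual estimator failures
#' yield `NA` fields rather than errors.
#'
#' @param wf A [waveform].
#' @param f0_min,f0_max Pitch range in Hz.
#' @param classical Use classical jitter/shimmer definitions.
#' @return Named numeric vector with the 17 acoustic feature names.
#' @export
acoustic_features <- function(wf, f0_min = 60, f0_max = 500, classical = FALSE) {
  out <- stats::setNames(rep(NA_real_, 17L), feature_names()[1:17])
  cs <- tryCatch(estimate_cycles(wf, f0_min, f0_max), vm_error = function(e) NULL)
  if (!is.null(cs)) {
    out["F0"] <- mean(1 / cs$periods)
    jt <- tryCatch(jitter_metrics(cs, classical = classical, require_all = FALSE),
                   vm_error = function(e) NULL)
    if (!is.null(jt)) {
      out[c("Jitter_abs", "Jitter_rel", "Jitter_RAP", "Jitter_PPQ5",
            "Jitter_DDP")] <- unlist(jt)
    }
    sh <- tryCatch(shimmer_metrics(cs, classical = classical, require_all = FALSE),
                   vm_error = function(e) NULL)
    if (!is.null(sh)) {
      out[c("Shim_rel", "Shim_dB", "Shim_APQ3", "Shim_APQ5", "Shim_APQ11",
            "Shim_DDA")] <- unlist(sh)
    }
    out["HNR"] <- tryCatch(harmonic_noise_ratio(wf, cs),
                           vm_error = function(e) NA_real_)
  }
  fs <- tryCatch(estimate_formants(wf, 4, f0_min, f0_max),
                 vm_error = function(e) NULL)
  if (!is.null(fs)) {
    out[c("F1", "F2", "F3", "F4")] <- c(fs$F1, fs$F2, fs$F3, fs$F4)
    if (!is.null(cs)) out["F0"] <- fs$F0
  }
  out
}
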