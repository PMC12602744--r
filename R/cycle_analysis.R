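# Glottal cycle and formant estimation.
#
# Pitch/cycle method: a coarse F0 track from the normalized autocorrelation of
# 40 ms frames, then waveform peak-picking within +/-30% of the local period
# to fix cycle landmarks, with parabolic interpolation for sub-sample peak
# positions. Frames whose autocorrelation peak falls below the voicing gate
# are unvoiced; speech items contribute only their voiced stretches, each
# contiguous stretch analyzed separately and the cycle series concatenated.

#' Construct a cycle series
#'
#' Ordered glottal-cycle periods and peak-to-peak amplitudes: the substrate
#' of all jitter/shimmer metrics.
#'
#' @param periods Cycle durations in seconds (all `> 0`).
#' @param amplitudes Per-cycle peak-to-peak amplitudes (all `>= 0`), same
#'   length as `periods`.
#' @param onsets Optional cycle landmark times in seconds (length
#'   `length(periods) + 1` when given), kept for cycle-synchronous analysis.
#' @param runs Optional list of per-voiced-run landmark vectors (seconds).
#' @return An object of class `cycle_series`.
#' @export
cycle_series <- function(periods, amplitudes, onsets = NULL, runs = NULL) {
  vm_check(length(periods) == length(amplitudes) && length(periods) >= 2L,
           "vm_parameter_error",
           "periods and amplitudes must have equal length >= 2")
  vm_check(all(periods > 0), "vm_parameter_error", "all periods must be > 0")
  vm_check(all(amplitudes >= 0), "vm_parameter_error",
           "all amplitudes must be >= 0")
  structure(list(periods = as.numeric(periods),
                 amplitudes = as.numeric(amplitudes),
                 n = length(periods), onsets = onsets, runs = runs),
            class = "cycle_series")
}

#' @export
print.cycle_series <- function(x, ...) {
  cat(sprintf("<cycle_series> %d cycles, mean period %.5f s (%.1f Hz)\n",
              x$n, mean(x$periods), 1 / mean(x$periods)))
  invisible(x)
}

# Normalized autocorrelation of one frame over a lag range; returns the best
# lag (parabolic-refined) and its correlation value.
frame_autocorr_peak <- function(x, lag_min, lag_max) {
  n <- length(x)
  x <- x - mean(x)
  lags <- lag_min:min(lag_max, n - 2L)
  r <- vapply(lags, function(l) {
    a <- x[1:(n - l)]; b <- x[(1 + l):n]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den < 1e-30) 0 else sum(a * b) / den
  }, numeric(1))
  rmax <- max(r)
  # octave-error guard: among local maxima, prefer the shortest lag whose
  # correlation is within 10% of the best (subharmonics score similarly)
  is_lmax <- c(FALSE, r[-c(1, length(r))] >= r[-(1:2)] &
                 r[-c(1, length(r))] >= r[-c(length(r) - 1, length(r))], FALSE)
  cand <- which(is_lmax & r >= 0.9 * rmax)
  i <- if (length(cand)) cand[1] else which.max(r)
  lag <- lags[i]
  if (i > 1L && i < length(r)) {  # parabolic refinement
    d <- (r[i - 1] - r[i + 1]) / (2 * (r[i - 1] - 2 * r[i] + r[i + 1]))
    if (is.finite(d) && abs(d) < 1) lag <- lag + d
  }
  list(lag = lag, r = rmax)
}

# Parabolically refined position/value of a local maximum at index i.
refine_peak <- function(x, i) {
  if (i <= 1L || i >= length(x)) return(list(pos = i, val = x[i]))
  y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
  den <- y0 - 2 * y1 + y2
  if (abs(den) < 1e-30) return(list(pos = i, val = y1))
  d <- 0.5 * (y0 - y2) / den
  list(pos = i + max(-0.5, min(0.5, d)), val = y1 - 0.25 * (y0 - y2) * d)
}

#' Estimate glottal cycles
#'
#' @param wf A [waveform] with voiced content.
#' @param f0_min,f0_max Pitch search range in Hz.
#' @param voicing_threshold Normalized-autocorrelation gate below which a
#'   frame counts as unvoiced.
#' @return A [cycle_series()] whose periods are successive differences of the
#'   detected cycle landmarks and whose amplitudes are per-cycle peak-to-peak
#'   values.
#' @export
estimate_cycles <- function(wf, f0_min = 60, f0_max = 500,
                            voicing_threshold = 0.45) {
  stopifnot(inherits(wf, "waveform"))
  sr <- wf$sample_rate
  vm_check(f0_min > 0 && f0_min < f0_max && f0_max < sr / 2,
           "vm_parameter_error", "need 0 < f0_min < f0_max < sample_rate/2")
  x <- wf$samples
  frame_len <- round(0.04 * sr); hop <- round(0.02 * sr)
  if (length(x) < frame_len) {
    vm_stop("vm_insufficient_voicing", "signal shorter than one analysis frame")
  }
  # Low-passed copies spread narrow glottal pulses across the cycle so the
  # autocorrelation survives realistic jitter; peak-picking below stays on
  # the raw signal. Two bands: a wider one for the voicing decision (noise
  # decorrelates there, so it is not mistaken for voicing) and a narrower
  # one for the period estimate (stronger cycle overlap suppresses octave
  # errors under jitter).
  lp <- function(cut) {
    if (cut < 0.49 * sr) {
      as.numeric(signal::filtfilt(signal::butter(4, cut / (sr / 2)), x))
    } else x
  }
  xa_voice <- lp(min(2.5 * f0_max, 0.45 * sr))
  xa_lag <- lp(min(1.5 * f0_max, 0.45 * sr))
  lag_min <- max(2L, floor(sr / f0_max))
  lag_max <- ceiling(sr / f0_min)
  n_frames <- (length(x) - frame_len) %/% hop + 1L
  voiced <- logical(n_frames); period_smp <- rep(NA_real_, n_frames)
  r_track <- rep(0, n_frames)
  for (i in seq_len(n_frames)) {
    fr <- xa_voice[((i - 1L) * hop + 1L):((i - 1L) * hop + frame_len)]
    if (stats::sd(fr) < 1e-8) next
    pk <- frame_autocorr_peak(fr, lag_min, lag_max)
    r_track[i] <- pk$r
    voiced[i] <- pk$r >= voicing_threshold
  }
  if (!any(voiced)) {
    vm_stop("vm_insufficient_voicing", "no voiced frames detected")
  }
  # hysteresis: marginal frames adjacent to voiced ones stay voiced, so a
  # perturbed-but-periodic stretch is not fragmented into many short runs
  lo_gate <- 0.6 * voicing_threshold
  repeat {
    grow <- !voiced & r_track >= lo_gate &
      (c(FALSE, voiced[-n_frames]) | c(voiced[-1], FALSE))
    if (!any(grow)) break
    voiced[grow] <- TRUE
  }
  for (i in which(voiced)) {
    fr <- xa_lag[((i - 1L) * hop + 1L):((i - 1L) * hop + frame_len)]
    period_smp[i] <- frame_autocorr_peak(fr, lag_min, lag_max)$lag
  }
  runs <- rle(voiced)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  all_landmarks <- list(); all_periods <- c(); all_amps <- c()
  for (ri in which(runs$values)) {
    fr_idx <- starts[ri]:ends[ri]
    if (length(fr_idx) < 2L) next
    seg_lo <- (fr_idx[1] - 1L) * hop + 1L
    seg_hi <- min(length(x), (fr_idx[length(fr_idx)] - 1L) * hop + frame_len)
    seg <- x[seg_lo:seg_hi]
    p_local <- stats::median(period_smp[fr_idx], na.rm = TRUE)
    lm <- pick_cycle_peaks(seg, p_local)
    if (length(lm) < 3L) next
    periods <- diff(lm) / sr
    # per-cycle peak-to-peak in a window centered on each landmark, with
    # parabolic refinement of both extrema for sub-sample amplitude accuracy
    amps <- vapply(seq_len(length(lm) - 1L), function(i) {
      half <- (lm[i + 1] - lm[i]) / 2
      lo <- max(1, round(lm[i] - half)); hi <- min(length(seg), round(lm[i] + half))
      w <- seg[lo:hi]
      pk <- refine_peak(w, which.max(w))$val
      tr <- -refine_peak(-w, which.min(w))$val
      pk - tr
    }, numeric(1))
    all_landmarks[[length(all_landmarks) + 1L]] <- (lm + seg_lo - 1) / sr
    all_periods <- c(all_periods, periods)
    all_amps <- c(all_amps, amps)
  }
  if (length(all_periods) < 5L) {
    vm_stop("vm_insufficient_voicing",
            sprintf("only %d cycles detected (need >= 5)", length(all_periods)))
  }
  f0_mean <- mean(1 / all_periods)
  if (f0_mean < f0_min || f0_mean > f0_max) {
    vm_stop("vm_insufficient_voicing",
            sprintf("mean cycle rate %.1f Hz outside [%g, %g]",
                    f0_mean, f0_min, f0_max))
  }
  onsets <- if (length(all_landmarks) == 1L) all_landmarks[[1]] else NULL
  cycle_series(all_periods, all_amps, onsets = onsets, runs = all_landmarks)
}

# March through a voiced segment picking one waveform peak per cycle, forward
# and backward from the global extremum, searching +/-30% around the local
# period estimate. Returns fractional sample positions within `seg`.
pick_cycle_peaks <- function(seg, period_smp) {
  n <- length(seg)
  pol <- if (abs(max(seg)) >= abs(min(seg))) 1 else -1
  s <- pol * seg
  anchor <- which.max(s)
  lo_f <- floor(0.7 * period_smp); hi_f <- ceiling(1.3 * period_smp)
  walk <- function(start, dir) {
    out <- c(); cur <- start
    repeat {
      w_lo <- cur + dir * lo_f; w_hi <- cur + dir * hi_f
      lo <- min(w_lo, w_hi); hi <- max(w_lo, w_hi)
      if (lo < 1 || hi > n) break
      lo_i <- max(1L, floor(lo)); hi_i <- min(n, ceiling(hi))
      if (hi_i - lo_i < 2L) break
      j <- lo_i - 1L + which.max(s[lo_i:hi_i])
      rp <- refine_peak(s, j)
      out <- c(out, rp$pos)
      cur <- rp$pos
    }
    out
  }
  a_ref <- refine_peak(s, anchor)
  sort(c(rev(walk(a_ref$pos, -1)), a_ref$pos, walk(a_ref$pos, +1)))
}

#' Estimate formant frequencies
#'
#' Linear-predictive analysis (model order 12) on the signal decimated to
#' roughly 11 kHz with 0.97 pre-emphasis; resonance candidates are complex
#' pole angles with bandwidth below 400 Hz. F0 comes from [estimate_cycles()].
#'
#' @param wf A [waveform] with voiced vowel content.
#' @param n_formants Number of formants requested (`<= 5`).
#' @param f0_min,f0_max Pitch range passed through to the cycle estimator.
#' @return A `formant_set`: list with `F0` and `F1`..`F4` (NA where fewer
#'   resonances were resolvable than requested, with a `missing` flag vector).
#' @export
estimate_formants <- function(wf, n_formants = 4, f0_min = 60, f0_max = 500) {
  stopifnot(inherits(wf, "waveform"))
  vm_check(n_formants >= 1 && n_formants <= 5, "vm_parameter_error",
           "n_formants must lie in 1..5")
  cs <- estimate_cycles(wf, f0_min, f0_max)   # also validates voicing
  f0 <- mean(1 / cs$periods)
  sr <- wf$sample_rate
  q <- max(1L, floor(sr / 11025))
  x <- wf$samples
  if (q > 1L) x <- signal::decimate(x, q)
  sr_d <- sr / q
  x <- x - mean(x)
  x <- c(x[1], x[-1] - 0.97 * x[-length(x)])   # pre-emphasis
  # autocorrelation averaged over Hamming-windowed 30 ms frames (50% hop):
  # averaging smooths the harmonic fine structure a single long window
  # would imprint on the envelope estimate
  # 12 poles per 5.5 kHz of analysis bandwidth (the conventional budget of
  # one resonance pair per kHz, plus source poles); when the rate admits no
  # integer decimation to ~11 kHz the order grows with the wider band
  p <- max(8L, as.integer(round(12 * sr_d / 11025)))
  n <- round(0.03 * sr_d); hop <- max(1L, n %/% 2L)
  if (length(x) < n) {
    vm_stop("vm_insufficient_voicing", "signal too short for formant analysis")
  }
  nf <- (length(x) - n) %/% hop + 1L
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  r <- numeric(p + 1L)
  for (f in seq_len(nf)) {
    fr <- x[((f - 1L) * hop + 1L):((f - 1L) * hop + n)] * ham
    r <- r + stats::acf(fr, lag.max = p, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  }
  r <- r / nf
  a <- tryCatch(solve(stats::toeplitz(r[1:p]), r[2:(p + 1L)]),
                error = function(e) NULL)
  freqs <- numeric(0); bws <- numeric(0)
  if (!is.null(a)) {
    roots <- polyroot(c(-rev(a), 1))
    ang <- Arg(roots); mod <- Mod(roots)
    keep <- ang > 0 & ang < pi
    f <- ang[keep] * sr_d / (2 * pi)
    bw <- -log(pmin(mod[keep], 0.999999)) * sr_d / pi
    ok <- f > 90 & f < sr_d / 2 - 50 & bw < 400
    ord <- order(f[ok])
    freqs <- f[ok][ord]; bws <- bw[ok][ord]
  }
  vals <- rep(NA_real_, n_formants)
  nf <- min(n_formants, length(freqs))
  if (nf > 0) vals[1:nf] <- freqs[1:nf]
  out <- as.list(c(F0 = f0, stats::setNames(vals, paste0("F", seq_len(n_formants)))))
  out$missing <- is.na(vals)
  out$bandwidths <- if (nf > 0) bws[1:nf] else numeric(0)
  structure(out, class = "formant_set")
}
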