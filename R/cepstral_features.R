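# Cepstral-domain features: MFCC statistics, cepstral peak prominence,
# zero-crossing rate, spectral centroid.
#
# MFCC follows the standard five-stage construction (framing, power spectrum,
# mel filterbank, log, DCT). The coefficient-by-frame matrix is flattened and
# summarized by its mean and median. CPP is the height of the dominant
# cepstral peak above a regression-line trend fit over the allowed quefrency
# band, per frame, in dB.

#' Default cepstral analysis configuration
#'
#' @param frame_length Analysis frame in samples (default 2048, ~46 ms at
#'   44.1 kHz).
#' @param hop Frame hop in samples.
#' @param n_mels Number of mel filters.
#' @param n_mfcc Number of cepstral coefficients kept.
#' @param f0_min,f0_max Pitch range bounding the CPP quefrency band (Hz).
#' @param highpass_hz CPP pre-filter cutoff (Hz).
#' @return A named list of settings.
#' @export
cepstral_config <- function(frame_length = 2048L, hop = 512L, n_mels = 26L,
                            n_mfcc = 13L, f0_min = 60, f0_max = 500,
                            highpass_hz = 60) {
  list(frame_length = as.integer(frame_length), hop = as.integer(hop),
       n_mels = as.integer(n_mels), n_mfcc = as.integer(n_mfcc),
       f0_min = f0_min, f0_max = f0_max, highpass_hz = highpass_hz)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank on the one-sided spectrum of an n_fft transform.
mel_filterbank <- function(n_mels, n_fft, sr, fmin = 0, fmax = sr / 2) {
  n_bins <- n_fft %/% 2L + 1L
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- (seq_len(n_bins) - 1L) * sr / n_fft
  fb <- matrix(0, nrow = n_mels, ncol = n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; mid <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bin_freqs - lo) / (mid - lo)
    down <- (hi - bin_freqs) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  m <- outer(0:(n_out - 1L), 0:(n_in - 1L), function(k, n) {
    cos(pi * k * (2 * n + 1) / (2 * n_in))
  })
  m * sqrt(2 / n_in)
}

#' MFCC matrix of a waveform
#'
#' @param wf A [waveform].
#' @param config A [cepstral_config()].
#' @return Matrix, one row per frame, `n_mfcc` columns.
#' @export
mfcc_matrix <- function(wf, config = cepstral_config()) {
  stopifnot(inherits(wf, "waveform"))
  fs <- frame_signal(wf, config$frame_length, config$hop, window = "hanning")
  n_fft <- config$frame_length
  fb <- mel_filterbank(config$n_mels, n_fft, wf$sample_rate)
  dct <- dct_matrix(config$n_mfcc, config$n_mels)
  n_bins <- n_fft %/% 2L + 1L
  out <- matrix(0, nrow = nrow(fs$frames), ncol = config$n_mfcc)
  for (i in seq_len(nrow(fs$frames))) {
    spec <- abs(stats::fft(fs$frames[i, ]))[1:n_bins]^2 / n_fft
    mel_e <- as.numeric(fb %*% spec)
    out[i, ] <- as.numeric(dct %*% log(mel_e + 1e-10))
  }
  out
}

#' Mean and median of the flattened MFCC matrix
#'
#' @param wf A [waveform].
#' @param config A [cepstral_config()].
#' @return List with `MFCC_mean` and `MFCC_median`.
#' @export
mfcc_stats <- function(wf, config = cepstral_config()) {
  m <- mfcc_matrix(wf, config)
  flat <- as.numeric(m)
  list(MFCC_mean = mean(flat), MFCC_median = stats::median(flat))
}

#' Cepstral peak prominence statistics
#'
#' Per frame: high-pass pre-filter, Hann window, real cepstrum of the dB
#' magnitude spectrum, peak picked inside the quefrency band corresponding to
#' `[f0_min, f0_max]`, and the value normalized by subtracting a linear
#' regression trend fit to the cepstrum over that band. Mean and median over
#' frames, in dB. Requires at least 3 analysis frames.
#'
#' @param wf A [waveform].
#' @param config A [cepstral_config()].
#' @return List with `CPP_mean` and `CPP_median` (dB).
#' @export
cpp_stats <- function(wf, config = cepstral_config()) {
  stopifnot(inherits(wf, "waveform"))
  sr <- wf$sample_rate
  hp <- highpass(wf, config$highpass_hz)
  n <- config$frame_length
  hop <- max(config$hop, n %/% 2L)      # CPP frames need length; use 50% overlap
  n_frames_avail <- if (length(hp$samples) >= n) {
    (length(hp$samples) - n) %/% hop + 1L
  } else 0L
  if (n_frames_avail < 3L) {
    vm_stop("vm_signal_too_short",
            sprintf("CPP needs >= 3 frames of %d samples (have %d)",
                    n, n_frames_avail))
  }
  fs <- frame_signal(hp, n, hop, window = "hanning")
  q_lo <- max(2L, floor(sr / config$f0_max))
  q_hi <- min(n %/% 2L - 1L, ceiling(sr / config$f0_min))
  vm_check(q_hi > q_lo + 4L, "vm_parameter_error",
           "quefrency band too narrow for this frame length")
  band <- q_lo:q_hi
  cpp <- numeric(nrow(fs$frames))
  for (i in seq_len(nrow(fs$frames))) {
    spec_db <- 20 * log10(abs(stats::fft(fs$frames[i, ])) + 1e-10)
    ceps <- Re(stats::fft(spec_db, inverse = TRUE)) / n
    cb <- ceps[band + 1L]
    pk <- which.max(cb)
    trend <- stats::lm.fit(cbind(1, band), cb)
    cpp[i] <- cb[pk] - sum(c(1, band[pk]) * trend$coefficients)
  }
  list(CPP_mean = mean(cpp), CPP_median = stats::median(cpp))
}

#' Zero-crossing rate statistics
#'
#' Per-frame ZCR is the number of sign changes divided by the frame length
#' (samples lying exactly on zero contribute half a change on each side, so a
#' crossing through an exact zero still counts once).
#'
#' @param frames A `frame_series` from [frame_signal()].
#' @return List with `ZCR_mean` and `ZCR_median` (crossings per sample).
#' @export
zcr_stats <- function(frames) {
  stopifnot(inherits(frames, "frame_series"))
  vm_check(nrow(frames$frames) >= 1L, "vm_parameter_error", "no frames")
  z <- apply(frames$frames, 1, function(fr) {
    sum(abs(diff(sign(fr)))) / 2 / length(fr)
  })
  list(ZCR_mean = mean(z), ZCR_median = stats::median(z))
}

#' Spectral centroid statistics
#'
#' Per-frame centroid is the magnitude-weighted mean frequency of the
#' one-sided spectrum; frames with RMS below `1e-6` are excluded rather than
#' contributing zero.
#'
#' @param frames A `frame_series` from [frame_signal()].
#' @return List with `SC_mean` and `SC_median` (Hz).
#' @export
centroid_stats <- function(frames) {
  stopifnot(inherits(frames, "frame_series"))
  n <- frames$frame_length
  sr <- frames$sample_rate
  n_bins <- n %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * sr / n
  sc <- apply(frames$frames, 1, function(fr) {
    if (sqrt(mean(fr^2)) < 1e-6) return(NA_real_)
    mag <- abs(stats::fft(fr))[1:n_bins]
    sum(freqs * mag) / sum(mag)
  })
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0L) vm_stop("vm_silent_input", "all frames are silent")
  list(SC_mean = mean(sc), SC_median = stats::median(sc))
}

#' All 8 cepstral-domain features of a recording
#'
#' @param wf A [waveform].
#' @param config A [cepstral_config()].
#' @return Named numeric vector of the 8 cepstral feature names (NA on
#'   individual extractor failure).
#' @export
cepstral_features <- function(wf, config = cepstral_config()) {
  out <- stats::setNames(rep(NA_real_, 8L), feature_names()[21:28])
  mf <- tryCatch(mfcc_stats(wf, config), vm_error = function(e) NULL)
  if (!is.null(mf)) out[c("MFCC_mean", "MFCC_median")] <- unlist(mf)
  cp <- tryCatch(cpp_stats(wf, config), vm_error = function(e) NULL)
  if (!is.null(cp)) out[c("CPP_mean", "CPP_median")] <- unlist(cp)
  fr <- tryCatch(frame_signal(wf, config$frame_length, config$hop),
                 vm_error = function(e) NULL)
  if (!is.null(fr)) {
    zc <- tryCatch(zcr_stats(fr), vm_error = function(e) NULL)
    if (!is.null(zc)) out[c("ZCR_mean", "ZCR_median")] <- unlist(zc)
    sc <- tryCatch(centroid_stats(fr), vm_error = function(e) NULL)
    if (!is.null(sc)) out[c("SC_mean", "SC_median")] <- unlist(sc)
  }
  out
}
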