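#' The 28 biomarker names, in canonical order
#'
#' 17 acoustic (F0, four formants, five jitter metrics, six shimmer metrics,
#' HNR), 3 articulation (TVSA, QVSA, FCR) and 8 cepstral (mean/median of
#' MFCC, CPP, ZCR, spectral centroid) features.
#'
#' @return Character vector of length 28.
#' @export
feature_names <- function() {
  c("F0", "F1", "F2", "F3", "F4",
    "Jitter_abs", "Jitter_rel", "Jitter_RAP", "Jitter_PPQ5", "Jitter_DDP",
    "Shim_rel", "Shim_dB", "Shim_APQ3", "Shim_APQ5", "Shim_APQ11", "Shim_DDA",
    "HNR",
    "TVSA", "QVSA", "FCR",
    "MFCC_mean", "MFCC_median", "CPP_mean", "CPP_median",
    "ZCR_mean", "ZCR_median", "SC_mean", "SC_median")
}
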