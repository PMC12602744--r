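#' Construct a waveform object
#'
#' A `waveform` is the raw input of every feature extractor: a mono sample
#' series in `[-1, 1]` with its sampling rate and recording metadata
#' (subject, class label, content tag).
#'
#' @param samples Numeric vector of amplitudes, `max(abs(samples)) <= 1`.
#' @param sample_rate Sampling rate in Hz.
#' @param subject_id Subject identifier string.
#' @param class_label Integer class (0 healthy, 1 PD, 2 MS) or `NA` if unknown.
#' @param content One of `"a"`, `"e"`, `"i"`, `"o"`, `"u"`, `"speech"`, or
#'   `NA` if unknown.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate, subject_id = NA_character_,
                     class_label = NA_integer_, content = NA_character_) {
  vm_check(is.numeric(samples) && length(samples) >= 1L,
           "vm_parameter_error", "samples must be a non-empty numeric vector")
  vm_check(is.numeric(sample_rate) && length(sample_rate) == 1L && sample_rate > 0,
           "vm_parameter_error", "sample_rate must be a positive scalar")
  vm_check(max(abs(samples)) <= 1 + 1e-9,
           "vm_parameter_error", "samples must lie in [-1, 1]")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         subject_id = subject_id, class_label = class_label, content = content),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)", length(x$samples),
              x$sample_rate, length(x$samples) / x$sample_rate))
  if (!is.na(x$subject_id)) cat(" subject:", x$subject_id)
  if (!is.na(x$content)) cat(" content:", x$content)
  if (!is.na(x$class_label)) cat(" class:", x$class_label)
  cat("\n")
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wf A `waveform`.
#' @return Duration in seconds.
#' @export
wf_duration <- function(wf) length(wf$samples) / wf$sample_rate
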