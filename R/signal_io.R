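# Audio I/O, framing and pre-processing filters.
#
# WAV support is a minimal RIFF PCM 16-bit codec: the acquisition protocol
# stores uncompressed PCM mono, and that is all the pipeline needs.

#' Read a RIFF PCM WAV file
#'
#' Reads 16-bit (or 8/32-bit integer) PCM WAV. Samples are rescaled to
#' `[-1, 1]`; stereo is downmixed by channel averaging. Subject, content and
#' take metadata are parsed from the `<subject>/<content>_<k>.wav` naming
#' convention when the path matches it.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform].
#' @export
read_wav <- function(path) {
  vm_check(file.exists(path), "vm_io_error", paste("file not found:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    vm_stop("vm_unsupported_format", paste("not a RIFF file:", path))
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    vm_stop("vm_unsupported_format", paste("not a WAVE file:", path))
  }
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, size = 4,
                               endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, size = 2,
                               endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0L) {
    vm_stop("vm_unsupported_format", paste("missing fmt/data chunk:", path))
  }
  if (fmt$audio_format != 1L) {
    vm_stop("vm_unsupported_format",
            paste0("unsupported (non-PCM) audio format ", fmt$audio_format))
  }
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- switch(as.character(fmt$bits),
    "8"  = (readBin(data_raw, "integer", n, size = 1, signed = FALSE) - 128) / 128,
    "16" = readBin(data_raw, "integer", n, size = 2, endian = "little") / 32768,
    "32" = readBin(data_raw, "integer", n, size = 4, endian = "little") / 2147483648,
    vm_stop("vm_unsupported_format", paste("unsupported bit depth:", fmt$bits))
  )
  if (fmt$n_channels > 1L) {
    x <- rowMeans(matrix(x, ncol = fmt$n_channels, byrow = TRUE))
  }
  meta <- parse_recording_path(path)
  waveform(x, fmt$sample_rate, subject_id = meta$subject_id,
           content = meta$content)
}

#' Write a waveform to a RIFF PCM 16-bit mono WAV file
#'
#' @param wf A [waveform].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wf, path) {
  stopifnot(inherits(wf, "waveform"))
  pcm <- as.integer(round(pmax(pmin(wf$samples, 1), -1) * 32768))
  pcm <- pmin(pmax(pcm, -32768L), 32767L)
  sr <- as.integer(round(wf$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# Parse subject/content/take from "<subject>/<content>_<k>.wav"; NAs when the
# path does not follow the convention.
parse_recording_path <- function(path) {
  fname <- tools::file_path_sans_ext(basename(path))
  subject <- basename(dirname(path))
  m <- regmatches(fname, regexec("^([aeiou]|speech)_([0-9]+)$", fname))[[1]]
  if (length(m) == 3L) {
    list(subject_id = subject, content = m[2], take = as.integer(m[3]))
  } else {
    list(subject_id = NA_character_, content = NA_character_, take = NA_integer_)
  }
}

#' Slice a signal into fixed-length, windowed frames
#'
#' The number of frames is `floor((N - frame_length)/hop) + 1`; trailing
#' samples that do not fill a frame are dropped. The window is applied
#' multiplicatively to every frame.
#'
#' @param wf A [waveform] or numeric vector.
#' @param frame_length Frame length in samples.
#' @param hop Hop between frame starts in samples (`>= 1`).
#' @param window `"rectangular"` or `"hanning"`.
#' @param sample_rate Required when `wf` is a bare numeric vector.
#' @return A `frame_series`: list with a `frames` matrix (one row per frame),
#'   `frame_length`, `hop`, `window`, `sample_rate`.
#' @export
frame_signal <- function(wf, frame_length, hop, window = c("rectangular", "hanning"),
                         sample_rate = NULL) {
  window <- match.arg(window)
  if (inherits(wf, "waveform")) {
    x <- wf$samples; sr <- wf$sample_rate
  } else {
    x <- as.numeric(wf); sr <- sample_rate
    vm_check(!is.null(sr), "vm_parameter_error",
             "sample_rate required for bare numeric input")
  }
  frame_length <- as.integer(frame_length); hop <- as.integer(hop)
  vm_check(hop >= 1L, "vm_parameter_error", "hop must be >= 1")
  n <- length(x)
  if (frame_length > n) {
    vm_stop("vm_signal_too_short",
            sprintf("signal (%d samples) shorter than frame_length (%d)", n, frame_length))
  }
  n_frames <- (n - frame_length) %/% hop + 1L
  w <- if (window == "hanning") hanning_window(frame_length) else rep(1, frame_length)
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- matrix(0, nrow = n_frames, ncol = frame_length)
  for (i in seq_len(n_frames)) {
    frames[i, ] <- x[(starts[i] + 1L):(starts[i] + frame_length)] * w
  }
  structure(list(frames = frames, frame_length = frame_length, hop = hop,
                 window = window, sample_rate = sr),
            class = "frame_series")
}

# Periodic Hann window (matches the DFT-analysis convention).
hanning_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), so
#' waveform landmarks (glottal cycle peaks) are not displaced in time.
#'
#' @param wf A [waveform].
#' @param cutoff_hz Cutoff frequency, `0 < cutoff_hz < sample_rate/2`.
#' @return The filtered [waveform].
#' @export
highpass <- function(wf, cutoff_hz = 60) {
  stopifnot(inherits(wf, "waveform"))
  nyq <- wf$sample_rate / 2
  vm_check(is.numeric(cutoff_hz) && length(cutoff_hz) == 1L &&
             cutoff_hz > 0 && cutoff_hz < nyq,
           "vm_parameter_error", "cutoff_hz must lie in (0, sample_rate/2)")
  bf <- signal::butter(4, cutoff_hz / nyq, type = "high")
  # remove the mean first: DC sits deep in the stopband anyway, and doing so
  # avoids filtfilt edge transients on offset signals
  y <- signal::filtfilt(bf, wf$samples - mean(wf$samples))
  out <- wf
  out$samples <- pmax(pmin(y, 1), -1)
  out
}
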