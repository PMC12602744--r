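# Synthetic voice generation.
#
# The generator produces quasi-periodic glottal pulse trains with controllable
# cycle-to-cycle period perturbation (jitter), amplitude perturbation
# (shimmer), harmonic-to-noise ratio and vowel formant structure. Every
# generator is a pure function of its spec (including the seed) and carries a
# ground-truth sidecar (clean/noise components, exact pulse times and
# amplitudes) so downstream extractors can be validated against known truth
# instead of against the pitch tracker under test.

#' Built-in vowel formant presets
#'
#' Center frequencies (Hz) of the first four formants for the five cardinal
#' vowels, adult-male values in the classic Peterson–Barney range, with
#' conventional bandwidths.
#'
#' @param vowel One of `"a"`, `"e"`, `"i"`, `"o"`, `"u"`.
#' @return A two-column matrix `cbind(center, bandwidth)` with four rows.
#' @export
vowel_formant_preset <- function(vowel) {
  presets <- list(
    a = c(730, 1090, 2440, 3400),
    e = c(530, 1840, 2480, 3500),
    i = c(270, 2290, 3010, 3700),
    o = c(570,  840, 2410, 3300),
    u = c(300,  870, 2240, 3200)
  )
  vm_check(is.character(vowel) && length(vowel) == 1L && vowel %in% names(presets),
           "vm_parameter_error", "vowel must be one of a, e, i, o, u")
  cbind(center = presets[[vowel]], bandwidth = c(80, 90, 120, 160))
}

#' Specification of a synthetic glottal pulse train
#'
#' @param f0 Fundamental frequency in Hz (`0 < f0 < sample_rate/2`).
#' @param duration Duration in seconds (must cover at least 5 cycles).
#' @param sample_rate Sampling rate in Hz. The default matches the 44 kHz
#'   acquisition protocol.
#' @param jitter_rel Target relative period perturbation (mean absolute
#'   consecutive period difference over mean period), in `[0, 0.2]`.
#' @param shimmer_rel Target relative amplitude perturbation, in `[0, 0.2]`.
#' @param hnr_db Target harmonic-to-noise power ratio in dB; `Inf` for a
#'   noiseless train.
#' @param formants Optional matrix `cbind(center, bandwidth)` of resonances,
#'   centers strictly increasing and below Nyquist.
#' @param vowel_label Optional vowel tag in `{a,e,i,o,u}`; if set and
#'   `formants` is `NULL`, the built-in preset is used by [generate_vowel()].
#' @param seed Integer seed; generators are deterministic given the spec.
#' @return An object of class `pulse_train_spec`.
#' @export
pulse_train_spec <- function(f0 = 120, duration = 1, sample_rate = 44100,
                             jitter_rel = 0, shimmer_rel = 0, hnr_db = Inf,
                             formants = NULL, vowel_label = NA_character_,
                             seed = 1L) {
  vm_check(is.numeric(f0) && f0 > 0 && f0 < sample_rate / 2,
           "vm_parameter_error", "f0 must lie in (0, sample_rate/2)")
  vm_check(is.numeric(duration) && duration > 0,
           "vm_parameter_error", "duration must be positive")
  vm_check(jitter_rel >= 0 && jitter_rel <= 0.2,
           "vm_parameter_error", "jitter_rel must lie in [0, 0.2]")
  vm_check(shimmer_rel >= 0 && shimmer_rel <= 0.2,
           "vm_parameter_error", "shimmer_rel must lie in [0, 0.2]")
  vm_check(is.numeric(hnr_db) && length(hnr_db) == 1L,
           "vm_parameter_error", "hnr_db must be a numeric scalar (Inf for noiseless)")
  if (!is.null(formants)) {
    formants <- as.matrix(formants)
    vm_check(ncol(formants) == 2L && all(formants > 0) &&
               all(diff(formants[, 1]) > 0) &&
               all(formants[, 1] < sample_rate / 2),
             "vm_parameter_error",
             "formant centers must be strictly increasing and below Nyquist")
  }
  if (!is.na(vowel_label)) {
    vm_check(vowel_label %in% c("a", "e", "i", "o", "u"),
             "vm_parameter_error", "vowel_label must be one of a, e, i, o, u")
  }
  structure(list(f0 = f0, duration = duration, sample_rate = sample_rate,
                 jitter_rel = jitter_rel, shimmer_rel = shimmer_rel,
                 hnr_db = hnr_db, formants = formants,
                 vowel_label = vowel_label, seed = as.integer(seed)),
            class = "pulse_train_spec")
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards, so generators are pure functions of their spec.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Zero-mean Gaussian perturbations truncated at +/- 3 sd, scaled so that the
# *realized* mean |x_i - x_{i-1}| of a long perturbed series matches `target`
# relative perturbation: for eps ~ N(0, s), E|eps_i - eps_{i-1}| = 2 s / sqrt(pi).
perturbation_draw <- function(n, target) {
  if (target <= 0) return(rep(0, n))
  s <- target * sqrt(pi) / 2
  pmin(pmax(stats::rnorm(n, 0, s), -3 * s), 3 * s)
}

#' Generate a quasi-periodic glottal pulse train
#'
#' Each cycle is a smooth unipolar raised-cosine burst; cycle periods are
#' `T0 * (1 + eps_i)` and cycle peak amplitudes `1 + delta_i`, with `eps`,
#' `delta` zero-mean truncated Gaussians calibrated so the realized relative
#' perturbations match `jitter_rel` / `shimmer_rel`. Band-limited Gaussian
#' noise is added to meet `hnr_db` exactly (measured on the stored
#' components). The returned waveform carries a `ground_truth` attribute with
#' `pulse_times` (exact pulse center times, seconds), `pulse_amps`, `clean`
#' and `noise` components, all on the same post-normalization scale.
#'
#' @param spec A [pulse_train_spec()].
#' @return A [waveform] with a `ground_truth` attribute.
#' @export
generate_pulse_train <- function(spec) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  sr <- spec$sample_rate
  T0 <- 1 / spec$f0
  if (spec$duration < 5 * T0) {
    vm_stop("vm_signal_too_short",
            sprintf("duration %.3fs covers fewer than 5 cycles of f0=%g Hz",
                    spec$duration, spec$f0))
  }
  n_total <- floor(spec$duration * sr)
  with_local_seed(spec$seed, {
    n_max <- ceiling(spec$duration * spec$f0) + 10L
    eps <- perturbation_draw(n_max, spec$jitter_rel)
    delta <- perturbation_draw(n_max, spec$shimmer_rel)
    periods <- T0 * (1 + eps)
    amps <- pmax(1 + delta, 0.05)
    # narrow smooth burst: wide enough to stay band-limited and smooth for
    # cepstral analysis, narrow enough to excite resonances up to F4
    width <- min(0.4 * T0, 0.00025)
    centers <- width / 2 + c(0, cumsum(periods))
    keep <- centers <= spec$duration - width / 2 - 1 / sr
    centers <- centers[keep]
    amps <- amps[seq_along(centers)]
    clean <- numeric(n_total)
    half_n <- round(width / 2 * sr)
    for (i in seq_along(centers)) {
      c_idx <- centers[i] * sr             # fractional sample position
      idx <- max(0, floor(c_idx - half_n)):min(n_total - 1, ceiling(c_idx + half_n))
      phase <- (idx - c_idx) / (2 * half_n)  # in [-0.5, 0.5] over the support
      burst <- amps[i] * (0.5 + 0.5 * cos(2 * pi * phase))
      burst[abs(phase) > 0.5] <- 0
      clean[idx + 1L] <- clean[idx + 1L] + burst
    }
    noise <- numeric(n_total)
    if (is.finite(spec$hnr_db)) {
      raw <- stats::rnorm(n_total)
      bf <- signal::butter(4, c(50 / (sr / 2), 0.9), type = "pass")
      raw <- signal::filtfilt(bf, raw)
      p_clean <- mean(clean^2)
      p_noise_target <- p_clean / 10^(spec$hnr_db / 10)
      noise <- raw * sqrt(p_noise_target / mean(raw^2))
    }
    mix <- clean + noise
    peak <- max(abs(mix))
    scl <- if (peak > 1) 0.999 / peak else 1
    wf <- waveform(mix * scl, sr, content = spec$vowel_label)
    attr(wf, "ground_truth") <- list(
      pulse_times = centers, pulse_amps = amps * scl,
      clean = clean * scl, noise = noise * scl, spec = spec
    )
    wf
  })
}

# Second-order resonator (two-pole) filter with unit peak gain.
resonator_apply <- function(x, center, bandwidth, sr) {
  r <- exp(-pi * bandwidth / sr)
  theta <- 2 * pi * center / sr
  a <- c(1, -2 * r * cos(theta), r^2)
  # normalize to unit magnitude response at the resonance frequency
  z <- exp(1i * theta)
  g <- abs(a[1] + a[2] / z + a[3] / z^2)
  as.numeric(signal::filter(signal::Arma(b = g, a = a), x))
}

#' Generate a synthetic sustained vowel
#'
#' A glottal pulse train filtered through cascaded second-order resonators at
#' the vowel formant frequencies. Noise is passed through the same vocal-tract
#' filter and rescaled afterwards, so the stored clean/noise components meet
#' `hnr_db` exactly after filtering.
#'
#' @param spec A [pulse_train_spec()] with `vowel_label` set (formants taken
#'   from the built-in preset when not given explicitly).
#' @return A [waveform] with a `ground_truth` attribute.
#' @export
generate_vowel <- function(spec) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  vm_check(!is.na(spec$vowel_label) || !is.null(spec$formants),
           "vm_parameter_error", "vowel_label or formants must be provided")
  formants <- spec$formants
  if (is.null(formants)) formants <- vowel_formant_preset(spec$vowel_label)
  vm_check(all(formants[, 1] < spec$sample_rate / 2),
           "vm_parameter_error", "formant centers must be below Nyquist")
  src_spec <- spec
  src_spec$formants <- NULL
  src <- generate_pulse_train(src_spec)
  gt <- attr(src, "ground_truth")
  sr <- spec$sample_rate
  filt <- function(x) {
    for (j in seq_len(nrow(formants))) {
      x <- resonator_apply(x, formants[j, 1], formants[j, 2], sr)
    }
    x
  }
  clean <- filt(gt$clean)
  noise <- gt$noise
  if (is.finite(spec$hnr_db) && any(noise != 0)) {
    noise <- filt(noise)
    noise <- noise * sqrt(mean(clean^2) / 10^(spec$hnr_db / 10) / mean(noise^2))
  }
  mix <- clean + noise
  peak <- max(abs(mix))
  scl <- if (peak > 0) 0.97 / peak else 1
  wf <- waveform(mix * scl, sr, content = spec$vowel_label)
  attr(wf, "ground_truth") <- list(
    pulse_times = gt$pulse_times,
    pulse_amps = gt$pulse_amps,   # relative pattern; scale is source-domain
    clean = clean * scl, noise = noise * scl, spec = spec,
    formants = formants
  )
  wf
}

#' Generate a recording session for one synthetic subject
#'
#' Mirrors the acquisition protocol: two phonations of each of the five
#' vowels plus one speech-like item (three short vowel segments separated by
#' 100 ms silences). All recordings are tagged with the subject and class.
#'
#' @param subject_id Subject identifier.
#' @param class_label Class (0 healthy, 1 PD, 2 MS).
#' @param base_spec A [pulse_train_spec()] giving f0, duration, sample rate
#'   and perturbation levels for this subject.
#' @param seed Session seed; each recording derives its own sub-seed.
#' @return A list of 11 [waveform]s.
#' @export
generate_session <- function(subject_id, class_label, base_spec, seed = 1L) {
  stopifnot(inherits(base_spec, "pulse_train_spec"))
  vowels <- c("a", "e", "i", "o", "u")
  out <- list()
  k <- 0L
  for (v in vowels) {
    for (take in 1:2) {
      k <- k + 1L
      sp <- base_spec
      sp$vowel_label <- v
      sp$formants <- NULL
      sp$seed <- as.integer((seed * 131L + k) %% .Machine$integer.max)
      wf <- generate_vowel(sp)
      wf$subject_id <- subject_id
      wf$class_label <- class_label
      out[[sprintf("%s_%d", v, take)]] <- wf
    }
  }
  # speech-like item: concatenated short vowel segments with 100 ms pauses
  seg_dur <- max(0.2, base_spec$duration / 3)
  sil <- numeric(round(0.1 * base_spec$sample_rate))
  segs <- list()
  for (j in seq_along(vowels[1:3])) {
    sp <- base_spec
    sp$vowel_label <- vowels[j]
    sp$formants <- NULL
    sp$duration <- seg_dur
    sp$seed <- as.integer((seed * 131L + 50L + j) %% .Machine$integer.max)
    segs[[j]] <- generate_vowel(sp)$samples
  }
  speech <- c(sil, segs[[1]], sil, segs[[2]], sil, segs[[3]], sil)
  wf <- waveform(speech, base_spec$sample_rate, subject_id = subject_id,
                 class_label = class_label, content = "speech")
  out[["speech_1"]] <- wf
  out
}

#' Write a session to disk in the consolidation layout
#'
#' Writes `<root>/<subject_id>/<content>_<k>.wav` plus a JSON sidecar per
#' file carrying the class label and ground-truth pulse times when available.
#'
#' @param session List of [waveform]s from [generate_session()].
#' @param root Output root directory.
#' @return The subject directory path, invisibly.
#' @export
write_session <- function(session, root) {
  subject <- session[[1]]$subject_id
  dir <- file.path(root, subject)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in names(session)) {
    wf <- session[[name]]
    path <- file.path(dir, paste0(name, ".wav"))
    write_wav(wf, path)
    gt <- attr(wf, "ground_truth")
    sidecar <- list(subject_id = wf$subject_id, class_label = wf$class_label,
                    content = wf$content)
    if (!is.null(gt)) {
      sidecar$pulse_times <- gt$pulse_times
      sidecar$pulse_amps <- gt$pulse_amps
    }
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Specification of a synthetic class-conditional feature table
#'
#' Emulates the shape of the study table (records x 28 features) with
#' class-conditional Gaussian features and an optional missing-cell rate.
#'
#' @param n_per_class Named integer vector: records per class, names are the
#'   class labels.
#' @param class_means List (one entry per class) of length-28 mean vectors,
#'   or a single number recycled.
#' @param class_sds As `class_means`, standard deviations (all `> 0`).
#' @param missing_rate Fraction of feature cells blanked, in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return An object of class `feature_table_spec`.
#' @export
feature_table_spec <- function(n_per_class, class_means = 0, class_sds = 1,
                               missing_rate = 0, seed = 1L) {
  vm_check(length(n_per_class) >= 1L && all(n_per_class >= 1),
           "vm_parameter_error", "n_per_class must be a non-empty positive vector")
  vm_check(missing_rate >= 0 && missing_rate < 0.5,
           "vm_parameter_error", "missing_rate must lie in [0, 0.5)")
  k <- length(n_per_class)
  if (is.null(names(n_per_class))) names(n_per_class) <- as.character(seq_len(k) - 1L)
  expand <- function(v) {
    if (!is.list(v)) v <- rep(list(v), k)
    lapply(v, function(m) rep_len(as.numeric(m), 28L))
  }
  means <- expand(class_means)
  sds <- expand(class_sds)
  vm_check(all(unlist(sds) > 0), "vm_parameter_error", "all sds must be > 0")
  structure(list(n_per_class = n_per_class, class_means = means,
                 class_sds = sds, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "feature_table_spec")
}

#' Generate a class-conditional Gaussian feature table
#'
#' @param spec A [feature_table_spec()].
#' @return A data frame with `record_id`, `subject_id`, `content`,
#'   `class_label`, `augmented` and the 28 named feature columns.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "feature_table_spec"))
  with_local_seed(spec$seed, {
    classes <- names(spec$n_per_class)
    rows <- list()
    for (ci in seq_along(classes)) {
      n <- spec$n_per_class[[ci]]
      mu <- spec$class_means[[ci]]
      sd <- spec$class_sds[[ci]]
      x <- matrix(stats::rnorm(n * 28L), nrow = n)
      x <- sweep(sweep(x, 2, sd, "*"), 2, mu, "+")
      colnames(x) <- feature_names()
      rows[[ci]] <- data.frame(
        record_id = sprintf("c%s_r%03d", classes[ci], seq_len(n)),
        subject_id = sprintf("c%s_s%03d", classes[ci], seq_len(n)),
        content = "a", class_label = as.integer(classes[ci]),
        augmented = FALSE, x, stringsAsFactors = FALSE
      )
    }
    tbl <- do.call(rbind, rows)
    rownames(tbl) <- NULL
    if (spec$missing_rate > 0) {
      fcols <- feature_names()
      mask <- matrix(stats::runif(nrow(tbl) * 28L) < spec$missing_rate,
                     nrow = nrow(tbl))
      for (j in seq_along(fcols)) {
        tbl[[fcols[j]]][mask[, j]] <- NA_real_
      }
    }
    tbl
  })
}
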