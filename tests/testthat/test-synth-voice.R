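test_that("zero-perturbation noiseless train is exactly periodic", {
  wf <- quick_train(seed = 3, f0 = 100, dur = 1, sr = 44100)
  gt <- attr(wf, "ground_truth")
  intervals <- diff(gt$pulse_times)
  expect_true(all(abs(intervals - 0.01) <= 1 / 44100))
  expect_equal(length(gt$pulse_times), 100, tolerance = 0, ignore_attr = TRUE)
})

test_that("generators are deterministic in the seed and vary across seeds", {
  sp <- pulse_train_spec(f0 = 140, duration = 0.5, sample_rate = 16000,
                         jitter_rel = 0.01, shimmer_rel = 0.03, hnr_db = 20,
                         vowel_label = "a", seed = 11)
  expect_identical(generate_vowel(sp)$samples, generate_vowel(sp)$samples)
  sp2 <- sp; sp2$seed <- 12L
  expect_false(identical(generate_vowel(sp)$samples, generate_vowel(sp2)$samples))
})

test_that("realized jitter and shimmer of the sidecar match the target", {
  for (lev in c(0.005, 0.01, 0.02, 0.05)) {
    jr <- sapply(1:20, function(s) {
      gt <- attr(quick_train(seed = s, dur = 2, jitter = lev), "ground_truth")
      realized_perturbation(diff(gt$pulse_times))
    })
    expect_lt(abs(mean(jr) - lev) / lev, 0.2)
    sh <- sapply(1:20, function(s) {
      gt <- attr(quick_train(seed = s, dur = 2, shimmer = lev), "ground_truth")
      realized_perturbation(gt$pulse_amps)
    })
    expect_lt(abs(mean(sh) - lev) / lev, 0.2)
  }
})

test_that("stored clean/noise components meet the HNR target within 0.5 dB", {
  for (h in c(0, 10, 20, 30)) {
    gt <- attr(quick_train(seed = h + 1, dur = 1, hnr = h), "ground_truth")
    measured <- 10 * log10(mean(gt$clean^2) / mean(gt$noise^2))
    expect_lt(abs(measured - h), 0.5)
  }
  # vowel path re-calibrates after vocal-tract filtering
  v <- quick_vowel("o", seed = 2, dur = 0.6, hnr_db = 15)
  gt <- attr(v, "ground_truth")
  expect_lt(abs(10 * log10(mean(gt$clean^2) / mean(gt$noise^2)) - 15), 0.5)
})

test_that("invalid pulse-train specs are rejected", {
  expect_error(pulse_train_spec(f0 = 0), class = "vm_parameter_error")
  expect_error(pulse_train_spec(jitter_rel = 0.3), class = "vm_parameter_error")
  expect_error(pulse_train_spec(f0 = 9000, sample_rate = 16000),
               class = "vm_parameter_error")
  expect_error(
    generate_pulse_train(pulse_train_spec(f0 = 60, duration = 0.05)),
    class = "vm_signal_too_short")
  expect_error(
    generate_vowel(pulse_train_spec(f0 = 120, sample_rate = 16000,
                                    formants = cbind(c(700, 9000), c(90, 100)),
                                    vowel_label = "a")),
    class = "vm_parameter_error")
  expect_error(generate_vowel(pulse_train_spec(vowel_label = "x")),
               class = "vm_parameter_error")
})

test_that("vowel spectral envelope peaks near the preset F1 and F2", {
  v <- quick_vowel("a", seed = 5, f0 = 100, dur = 0.8)
  # averaged magnitude spectrum over 4096-sample frames
  fs <- frame_signal(v, 4096, 2048, window = "hanning")
  mag <- rep(0, 2049)
  for (i in seq_len(nrow(fs$frames))) {
    mag <- mag + abs(stats::fft(fs$frames[i, ]))[1:2049]
  }
  freqs <- (0:2048) * 44100 / 4096
  preset <- vowel_formant_preset("a")[, 1]
  for (target in preset[1:2]) {
    band <- which(freqs > target * 0.9 & freqs < target * 1.1)
    outside <- which(freqs > target * 0.7 & freqs < target * 1.3)
    # the local maximum over the wide neighborhood falls inside +/-10%
    expect_true(which.max(mag[outside]) %in% match(band, outside))
  }
})

test_that("sessions contain 10 vowel phonations and one speech item", {
  sp <- pulse_train_spec(f0 = 130, duration = 0.4, sample_rate = 16000,
                         jitter_rel = 0.01, seed = 2)
  sess <- generate_session("S01", 0L, sp, seed = 7)
  expect_length(sess, 11)
  contents <- vapply(sess, function(w) w$content, character(1))
  expect_equal(sort(unname(table(contents[contents != "speech"]))),
               c(2, 2, 2, 2, 2), ignore_attr = TRUE)
  expect_equal(sum(contents == "speech"), 1)
  expect_true(all(vapply(sess, function(w) w$subject_id == "S01", logical(1))))
  # different session seeds change samples but not structure
  sess2 <- generate_session("S01", 0L, sp, seed = 8)
  expect_false(identical(sess$a_1$samples, sess2$a_1$samples))
  expect_identical(names(sess), names(sess2))
})

test_that("pathological session has higher measured jitter than healthy", {
  base_h <- pulse_train_spec(f0 = 120, duration = 0.6, sample_rate = 16000,
                             jitter_rel = 0, seed = 1)
  base_p <- pulse_train_spec(f0 = 120, duration = 0.6, sample_rate = 16000,
                             jitter_rel = 0.04, seed = 1)
  mean_jit <- function(sess) {
    mean(vapply(sess[1:4], function(w) {
      gt <- attr(w, "ground_truth")
      realized_perturbation(diff(gt$pulse_times))
    }, numeric(1)))
  }
  expect_gt(mean_jit(generate_session("P", 1L, base_p, seed = 3)),
            mean_jit(generate_session("H", 0L, base_h, seed = 3)))
})

test_that("feature table generator honors counts, seeds and missing rate", {
  spec <- feature_table_spec(c("0" = 100, "1" = 100), missing_rate = 0, seed = 1)
  tbl <- generate_feature_table(spec)
  expect_equal(nrow(tbl), 200)
  expect_identical(intersect(feature_names(), names(tbl)), feature_names())
  expect_false(anyNA(tbl[, feature_names()]))
  expect_identical(generate_feature_table(spec), tbl)

  spec_m <- feature_table_spec(c("0" = 150, "1" = 150), missing_rate = 0.1,
                               seed = 4)
  tbl_m <- generate_feature_table(spec_m)
  frac <- mean(is.na(as.matrix(tbl_m[, feature_names()])))
  expect_lt(abs(frac - 0.1), 0.02)
  expect_error(feature_table_spec(integer(0)), class = "vm_parameter_error")
})
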