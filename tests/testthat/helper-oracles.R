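# Independent oracles: literal index-by-index transcriptions of the
# perturbation formulas, the shoelace polygon area, and direct metric
# formulas. These deliberately share no code with the implementation.

oracle_jitter <- function(T) {
  N <- length(T)
  denom <- sum(T[1:(N - 1)]) / N
  Ja <- sum(sapply(2:N, function(i) abs(T[i] - T[i - 1]))) / N
  Jr <- Ja / denom
  RAP <- (sum(sapply(2:(N - 1), function(i) {
    abs((T[i - 1] + T[i] + T[i + 1]) / 3 - T[i])
  })) / (N - 2)) / denom
  PPQ5 <- (sum(sapply(3:(N - 2), function(i) {
    abs((T[i - 2] + T[i - 1] + T[i] + T[i + 1] + T[i + 2]) / 5 - T[i])
  })) / (N - 4)) / denom
  DDP <- sum(sapply(2:N, function(i) abs(T[i] - T[i - 1]))) / (N - 1)
  list(Ja = Ja, Jr = Jr, RAP = RAP, PPQ5 = PPQ5, DDP = DDP)
}

oracle_shimmer <- function(A) {
  N <- length(A)
  denom <- sum(A[1:(N - 1)]) / N
  Sr <- (sum(sapply(1:(N - 1), function(i) abs(A[i] - A[i + 1]))) / (N - 1)) / denom
  SdB <- sum(sapply(1:(N - 1), function(i) 20 * log10(A[i + 1] / A[i]))) / (N - 1)
  apq <- function(n) {
    h <- n %/% 2
    if (N < 2 * h + 2) return(NA_real_)
    vals <- sapply((h + 1):(N - h), function(i) {
      nb <- A[i + setdiff(-h:h, 0)]
      abs(A[i] - mean(nb))
    })
    mean(vals) / mean(A)
  }
  DDA <- sum(sapply(2:N, function(i) abs(A[i] - A[i - 1]))) / (N - 1)
  list(Sr = Sr, SdB = SdB, APQ3 = apq(3), APQ5 = apq(5), APQ11 = apq(11),
       DDA = DDA)
}

oracle_shoelace <- function(xy) {
  # xy: matrix of polygon vertices in order
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

oracle_metrics <- function(TP, TN, FP, FN) {
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  total <- TP + TN + FP + FN
  prec <- TP / (TP + FP); sens <- TP / (TP + FN)
  list(Acc = (TP + TN) / total, Sens = sens, Spec = TN / (TN + FP),
       Prec = prec, F1 = 2 * prec * sens / (prec + sens),
       MCC = (TP * TN - FP * FN) /
         sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)))
}

# realized relative perturbation of a ground-truth series (mean absolute
# consecutive difference over the mean)
realized_perturbation <- function(v) mean(abs(diff(v))) / mean(v)

# short synthetic fixtures at a light sample rate for speed
quick_train <- function(seed = 1, f0 = 120, dur = 0.8, sr = 16000,
                        jitter = 0, shimmer = 0, hnr = Inf) {
  generate_pulse_train(pulse_train_spec(
    f0 = f0, duration = dur, sample_rate = sr, jitter_rel = jitter,
    shimmer_rel = shimmer, hnr_db = hnr, seed = seed))
}

quick_vowel <- function(vowel, seed = 1, f0 = 120, dur = 0.8, sr = 44100, ...) {
  generate_vowel(pulse_train_spec(f0 = f0, duration = dur, sample_rate = sr,
                                  vowel_label = vowel, seed = seed, ...))
}

# separable two-class feature table: class means 3 sd apart on 5 features
separated_table <- function(n = 100, seed = 42) {
  generate_feature_table(feature_table_spec(
    n_per_class = c("0" = n, "1" = n),
    class_means = list(rep(0, 28), c(rep(3, 5), rep(0, 23))),
    class_sds = 1, seed = seed))
}
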