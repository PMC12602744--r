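# Dataset assembly: per-record 28-feature vectors, folder consolidation to
# CSV, standardization with mean imputation, waveform-level augmentation and
# stratified record splitting.

meta_cols <- function() c("record_id", "subject_id", "content", "class_label",
                          "augmented")

#' Extract the 28-feature vector of one recording
#'
#' Individual extractor failures become `NA` fields and never abort the
#' record; the three articulation features are copied from the subject's
#' formant inventory (NA when the inventory is empty or lacks the corner
#' vowels).
#'
#' @param wf A [waveform].
#' @param subject_inventory A [formant_inventory()] or `NULL`.
#' @param f0_min,f0_max Pitch range in Hz.
#' @param config A [cepstral_config()].
#' @return Named numeric vector of length 28.
#' @export
extract_record_features <- function(wf, subject_inventory = NULL,
                                    f0_min = 60, f0_max = 500,
                                    config = cepstral_config()) {
  stopifnot(inherits(wf, "waveform"))
  out <- stats::setNames(rep(NA_real_, 28L), feature_names())
  out[1:17] <- acoustic_features(wf, f0_min, f0_max)
  if (!is.null(subject_inventory)) {
    art <- tryCatch(articulation_features(subject_inventory),
                    vm_error = function(e) NULL)
    if (!is.null(art)) out[c("TVSA", "QVSA", "FCR")] <- unlist(art)
  }
  out[21:28] <- cepstral_features(wf, config)
  out
}

#' Consolidate a directory of per-subject recordings into a feature table
#'
#' Walks `<root>/<subject>/<content>_<k>.wav`, estimates each subject's
#' formant inventory from their vowel phonations, extracts the 28 features of
#' every recording, and writes a structured CSV (one row per recording; a
#' corrupt file is skipped with a warning). Class labels are taken from the
#' JSON sidecars written by [write_session()] when present.
#'
#' @param root Root directory of per-subject folders.
#' @param csv_path Optional output CSV path (defaults to
#'   `file.path(root, "features.csv")`; `NA` to skip writing).
#' @param f0_min,f0_max Pitch range in Hz.
#' @param config A [cepstral_config()].
#' @return The feature table (data frame), invisibly carrying the CSV path
#'   as attribute `csv_path` when written.
#' @export
consolidate <- function(root, csv_path = file.path(root, "features.csv"),
                        f0_min = 60, f0_max = 500,
                        config = cepstral_config()) {
  vm_check(dir.exists(root), "vm_io_error", paste("no such directory:", root))
  subjects <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  files <- list()
  for (s in subjects) {
    wavs <- sort(list.files(file.path(root, s), pattern = "\\.wav$",
                            full.names = TRUE))
    if (length(wavs)) files[[s]] <- wavs
  }
  if (length(files) == 0L) {
    vm_stop("vm_empty_dataset", paste("no subject WAV files under", root))
  }
  rows <- list()
  for (s in names(files)) {
    recs <- list()
    for (path in files[[s]]) {
      wf <- tryCatch(read_wav(path), error = function(e) {
        warning(sprintf("skipping unreadable WAV %s: %s",
                        path, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(wf)) next
      wf$subject_id <- s
      side <- paste0(path, ".json")
      if (file.exists(side)) {
        meta <- jsonlite::read_json(side)
        if (!is.null(meta$class_label)) wf$class_label <- as.integer(meta$class_label)
        if (!is.null(meta$content)) wf$content <- meta$content
      }
      if (is.na(wf$content)) wf$content <- parse_recording_path(path)$content
      recs[[basename(path)]] <- wf
    }
    if (length(recs) == 0L) next
    # subject inventory from vowel recordings
    est <- do.call(rbind, lapply(names(recs), function(nm) {
      wf <- recs[[nm]]
      if (is.na(wf$content) || !wf$content %in% c("a", "e", "i", "o", "u")) {
        return(NULL)
      }
      fs <- tryCatch(estimate_formants(wf, 2, f0_min, f0_max),
                     vm_error = function(e) NULL)
      if (is.null(fs)) return(NULL)
      data.frame(vowel = wf$content, F1 = fs$F1, F2 = fs$F2)
    }))
    inv <- if (!is.null(est)) aggregate_inventory(est) else NULL
    for (nm in names(recs)) {
      wf <- recs[[nm]]
      fv <- extract_record_features(wf, inv, f0_min, f0_max, config)
      rows[[paste(s, nm, sep = "_")]] <- data.frame(
        record_id = paste(s, tools::file_path_sans_ext(nm), sep = "_"),
        subject_id = s, content = wf$content,
        class_label = wf$class_label, augmented = FALSE,
        t(fv), stringsAsFactors = FALSE
      )
    }
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  if (!is.na(csv_path)) {
    write_feature_csv(tbl, csv_path)
    attr(tbl, "csv_path") <- csv_path
  }
  tbl
}

#' Write a feature table as CSV
#'
#' Comma-separated, UTF-8, header row, empty cells for missing values,
#' numbers at 10 significant digits (so re-runs on unchanged inputs produce
#' byte-identical files).
#'
#' @param tbl Feature table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(tbl, path) {
  out <- tbl
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "",
                         formatC(out[[j]], format = "g", digits = 10))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Standardize a feature table (mean imputation, then z-scoring)
#'
#' Imputation first: missing cells take the column mean over `fit_rows`.
#' Then each feature column is centered and scaled with mean/sd estimated on
#' `fit_rows` only and applied to all rows (so test rows never leak into the
#' scaling). A zero-variance column is scaled by 1 with a warning; an
#' all-missing fitting column is an error naming the column.
#'
#' @param tbl Feature table data frame.
#' @param fit_rows Integer/logical index of the rows used to fit the
#'   parameters (default: all rows).
#' @return The standardized table, with attribute `scaling` (list of per-
#'   column `mean`, `sd`, `impute`).
#' @export
preprocess <- function(tbl, fit_rows = seq_len(nrow(tbl))) {
  fcols <- intersect(feature_names(), names(tbl))
  vm_check(length(fit_rows) >= 1L, "vm_parameter_error", "fit_rows is empty")
  means <- sds <- imputes <- stats::setNames(numeric(length(fcols)), fcols)
  out <- tbl
  for (col in fcols) {
    fit_vals <- tbl[[col]][fit_rows]
    if (all(is.na(fit_vals))) {
      vm_stop("vm_degenerate_column",
              paste("column has no non-missing fitting values:", col))
    }
    imp <- mean(fit_vals, na.rm = TRUE)
    v <- out[[col]]
    v[is.na(v)] <- imp
    fit_imp <- fit_vals
    fit_imp[is.na(fit_imp)] <- imp
    mu <- mean(fit_imp)
    sd <- sqrt(mean((fit_imp - mu)^2))   # population sd, scaler convention
    if (!is.finite(sd) || sd < 1e-12) {
      warning(sprintf("zero-variance column '%s'; sd replaced by 1", col),
              call. = FALSE)
      sd <- 1
    }
    out[[col]] <- (v - mu) / sd
    means[col] <- mu; sds[col] <- sd; imputes[col] <- imp
  }
  attr(out, "scaling") <- list(mean = means, sd = sds, impute = imputes,
                               fit_rows = fit_rows)
  out
}

#' Balance classes by augmenting minority-class recordings
#'
#' Operates on raw waveforms: minority classes are upsampled toward the
#' largest class by duplicating randomly chosen recordings with a small
#' uniform speed perturbation (resampling by a factor drawn from
#' `factor_range`), which changes duration and pitch together. Augmented
#' copies carry an `augmented` attribute and never enter test splits.
#'
#' @param records List of [waveform]s with class labels.
#' @param factor_range Length-2 range of perturbation factors, inside
#'   `(0.9, 1.1)` to guard against excessive deformation.
#' @param seed Integer seed.
#' @return The input list extended with the augmented copies.
#' @export
augment_minority <- function(records, factor_range = c(0.99, 1.01), seed = 1L) {
  vm_check(length(factor_range) == 2L && factor_range[1] <= factor_range[2] &&
             factor_range[1] > 0.9 && factor_range[2] < 1.1,
           "vm_parameter_error", "factor_range must lie inside (0.9, 1.1)")
  labels <- vapply(records, function(w) as.integer(w$class_label), integer(1))
  vm_check(!anyNA(labels), "vm_parameter_error",
           "all records need class labels for augmentation")
  counts <- table(labels)
  target <- max(counts)
  out <- records
  with_local_seed(seed, {
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need <= 0) next
      pool <- which(labels == as.integer(cl))
      src_idx <- pool[1L + (stats::runif(need) * length(pool)) %/% 1]
      for (j in seq_len(need)) {
        src <- records[[src_idx[j]]]
        fac <- stats::runif(1, factor_range[1], factor_range[2])
        n_new <- round(length(src$samples) * fac)
        y <- stats::approx(seq_along(src$samples), src$samples,
                           xout = seq(1, length(src$samples), length.out = n_new))$y
        aug <- waveform(y, src$sample_rate, subject_id = src$subject_id,
                        class_label = src$class_label, content = src$content)
        attr(aug, "augmented") <- TRUE
        attr(aug, "stretch_factor") <- fac
        out[[length(out) + 1L]] <- aug
      }
    }
  })
  out
}

#' Stratified train/test split of a feature table
#'
#' Test size is `round-half-up(test_fraction * N)`; per-class test quotas
#' follow the global class proportions (largest-remainder rounding, so every
#' class is within one record of its exact share). Augmented rows are never
#' placed in the test part.
#'
#' @param tbl Feature table with a `class_label` column (and optionally
#'   `augmented`).
#' @param test_fraction Fraction in `(0, 1)`.
#' @param seed Integer seed for the row shuffling.
#' @return List with data frames `train` and `test`.
#' @export
stratified_split <- function(tbl, test_fraction, seed = 1L) {
  vm_check(is.numeric(test_fraction) && length(test_fraction) == 1L &&
             test_fraction > 0 && test_fraction < 1,
           "vm_parameter_error", "test_fraction must lie in (0, 1)")
  n <- nrow(tbl)
  cls <- tbl$class_label
  vm_check(!anyNA(cls), "vm_parameter_error", "class_label has missing values")
  if (any(table(cls) < 2L)) {
    vm_stop("vm_stratification_error", "every class needs at least 2 rows")
  }
  aug <- if ("augmented" %in% names(tbl)) isTRUE_vec(tbl$augmented) else rep(FALSE, n)
  n_test <- floor(test_fraction * n + 0.5)
  classes <- sort(unique(cls))
  exact <- n_test * as.numeric(table(factor(cls, levels = classes))) / n
  quota <- floor(exact)
  rem <- n_test - sum(quota)
  if (rem > 0) {
    extra <- order(exact - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  test_idx <- integer(0)
  with_local_seed(seed, {
    for (ci in seq_along(classes)) {
      pool <- which(cls == classes[ci] & !aug)
      if (length(pool) < quota[ci]) {
        vm_stop("vm_stratification_error",
                sprintf("class %s has too few non-augmented rows for the test quota",
                        classes[ci]))
      }
      test_idx <- c(test_idx, sample(pool, quota[ci]))
    }
  })
  list(train = tbl[-test_idx, , drop = FALSE],
       test = tbl[sort(test_idx), , drop = FALSE])
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
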