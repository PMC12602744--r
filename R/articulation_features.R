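# Vowel-space articulation features: triangular and quadrilateral vowel
# space area and the formant centralization ratio, computed from per-subject
# corner-vowel (F1, F2) coordinates.

#' Build a per-subject formant inventory
#'
#' @param ... Named arguments `a=`, `e=`, `i=`, `o=`, `u=`, each a numeric
#'   vector `c(F1, F2)` with `F1 < F2`; vowels may be omitted.
#' @return An object of class `formant_inventory` (named list of c(F1, F2)).
#' @export
formant_inventory <- function(...) {
  inv <- list(...)
  vm_check(length(inv) >= 1L, "vm_parameter_error", "empty formant inventory")
  vm_check(all(names(inv) %in% c("a", "e", "i", "o", "u")),
           "vm_parameter_error", "inventory names must be vowels a,e,i,o,u")
  for (v in names(inv)) {
    f <- inv[[v]]
    vm_check(is.numeric(f) && length(f) == 2L && all(f > 0) && f[1] <= f[2],
             "vm_parameter_error",
             sprintf("vowel /%s/ needs positive c(F1, F2) with F1 <= F2", v))
  }
  structure(inv, class = "formant_inventory")
}

#' Vowel-space articulation features
#'
#' * `tVSA` — area (Hz^2) of the /i/–/a/–/u/ triangle in the (F1, F2) plane.
#' * `qVSA` — area (Hz^2) of the /i/–/e/–/a/–/u/ quadrilateral.
#' * `FCR`  — `(F2u + F2a + F1i + F1u) / (F2i + F1a)`; rises toward 2 as the
#'   corner vowels collapse toward their centroid.
#'
#' The area formulas are signed (vertex-orientation dependent); absolute
#' values are reported since an area is non-negative. Missing prerequisite
#' vowels yield `NA` fields rather than errors.
#'
#' @param inv A [formant_inventory()].
#' @return List with `tVSA`, `qVSA`, `FCR` (NA where prerequisites missing).
#' @export
articulation_features <- function(inv) {
  stopifnot(inherits(inv, "formant_inventory"))
  vm_check(length(inv) >= 1L, "vm_parameter_error", "empty formant inventory")
  F1 <- function(v) inv[[v]][1]
  F2 <- function(v) inv[[v]][2]
  has <- function(...) all(c(...) %in% names(inv))
  tVSA <- if (has("i", "u", "a")) {
    abs(F1("i") * (F2("a") - F2("u")) +
        F1("a") * (F2("u") - F2("i")) +
        F1("u") * (F2("i") - F2("a"))) / 2
  } else NA_real_
  qVSA <- if (has("i", "u", "e", "a")) {
    abs((F1("e") * F2("i") + F1("a") * F2("e") +
         F1("u") * F2("a") + F1("i") * F2("u")) -
        (F1("i") * F2("e") + F1("e") * F2("a") +
         F1("a") * F2("u") + F1("u") * F2("i"))) / 2
  } else NA_real_
  FCR <- if (has("i", "u", "a")) {
    (F2("u") + F2("a") + F1("i") + F1("u")) / (F2("i") + F1("a"))
  } else NA_real_
  list(tVSA = tVSA, qVSA = qVSA, FCR = FCR)
}

#' Aggregate an inventory from per-recording formant estimates
#'
#' Formants are averaged over a subject's available phonations of each vowel;
#' the resulting cross-vowel features are later broadcast onto every record
#' of that subject.
#'
#' @param estimates Data frame with columns `vowel`, `F1`, `F2` (one row per
#'   phonation; NAs dropped).
#' @return A [formant_inventory()], or `NULL` if no vowel has usable values.
#' @export
aggregate_inventory <- function(estimates) {
  est <- estimates[stats::complete.cases(estimates[, c("vowel", "F1", "F2")]), ,
                   drop = FALSE]
  est <- est[est$F1 > 0 & est$F2 > est$F1, , drop = FALSE]
  if (nrow(est) == 0L) return(NULL)
  args <- list()
  for (v in intersect(c("a", "e", "i", "o", "u"), unique(est$vowel))) {
    sub <- est[est$vowel == v, , drop = FALSE]
    args[[v]] <- c(mean(sub$F1), mean(sub$F2))
  }
  if (length(args) == 0L) return(NULL)
  do.call(formant_inventory, args)
}
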