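#' Compound consumption rate from a time course
#'
#' Fits a least-squares line to signal (concentration or proportional
#' absorbance) versus time over all replicate points and converts the
#' slope to a molar consumption rate:
#' `sigma_cc = -slope * n0 / intercept` (nmol/h), where `n0` is the
#' initial compound amount in the dosed medium and the intercept is the
#' regression's t = 0 value (not the earliest measured point). A positive
#' `sigma_cc` means net consumption. The formula is unit-invariant in the
#' signal: scaling every measurement scales slope and intercept together.
#'
#' @param table Data frame with columns `time_h` and
#'   `concentration_nmol_ml` (any proportional signal works), one row per
#'   replicate measurement; needs >= 3 distinct times.
#' @param n0 Initial compound amount, nmol (> 0).
#' @return Object of class `consumption_fit` with fields `sigma_abs`
#'   (signal/h slope), `abs0` (signal intercept), `n0`, `sigma_cc`
#'   (nmol/h), `r2` and `n_points`.
#' @export
#' @examples
#' tc <- data.frame(time_h = 0:10, concentration_nmol_ml = 100 - 10 * (0:10))
#' consumption_rate(tc, n0 = 100)$sigma_cc  # 10 nmol/h
consumption_rate <- function(table, n0) {
  assert_columns(table, c("time_h", "concentration_nmol_ml"), "table")
  assert_number(n0, "n0", positive = TRUE)
  t <- table$time_h
  y <- table$concentration_nmol_ml
  if (any(t < 0)) stopf("times must be non-negative")
  if (length(unique(t)) < 3L) {
    stopf("consumption rate needs >= 3 distinct time points")
  }
  fit <- stats::lm.fit(cbind(1, t), y)
  abs0 <- fit$coefficients[[1]]
  slope <- fit$coefficients[[2]]
  if (abs0 <= 0) {
    stopf("undefined consumption rate: regression intercept (Abs0) is <= 0")
  }
  structure(
    list(
      condition = if ("condition" %in% names(table)) as.character(table$condition[1]) else NA_character_,
      sigma_abs = slope,
      abs0 = abs0,
      n0 = n0,
      sigma_cc = -slope * n0 / abs0,
      r2 = safe_r2(y, y - fit$residuals),
      n_points = length(y)
    ),
    class = "consumption_fit"
  )
}

#' @export
print.consumption_fit <- function(x, ...) {
  cat("Compound consumption fit",
      if (!is.na(x$condition)) paste0(" [", x$condition, "]"), "\n", sep = "")
  cat(sprintf("  sigma_cc = %.4g nmol/h (slope %.4g signal/h, Abs0 %.4g, n0 %.4g nmol)\n",
              x$sigma_cc, x$sigma_abs, x$abs0, x$n0))
  cat(sprintf("  r2 = %.4f over %d points\n", x$r2, x$n_points))
  invisible(x)
}

#' Blank-corrected, mass-normalized consumption activity
#'
#' `activity = (sigma_cc_sample - sigma_cc_blank) / cc_mass` (nmol/h/ug):
#' the compound disappearance attributable to the cells, after deducting
#' abiotic degradation measured in the cell-free blank, normalized to the
#' initial compound mass in the dosed medium. A negative activity (blank
#' decaying faster than the sample) is reported with a warning rather than
#' floored — it is an informative QC signal.
#'
#' @param sample,blank [consumption_rate()] fits for the cell-containing
#'   sample and the cell-free blank.
#' @param cc_mass Initial compound mass, ug (> 0). See [curcumin_mass()].
#' @return Activity, nmol/h/ug.
#' @export
#' @examples
#' s <- structure(list(sigma_cc = 60), class = "consumption_fit")
#' b <- structure(list(sigma_cc = 10), class = "consumption_fit")
#' cc_activity(s, b, cc_mass = 1)  # 50
cc_activity <- function(sample, blank, cc_mass) {
  stopifnot(inherits(sample, "consumption_fit"),
            inherits(blank, "consumption_fit"))
  assert_number(cc_mass, "cc_mass")
  if (cc_mass <= 0) stopf("`cc_mass` must be > 0")
  activity <- (sample$sigma_cc - blank$sigma_cc) / cc_mass
  if (activity < 0) {
    warnf("negative consumption activity (%.4g nmol/h/ug): blank decays faster than sample",
          activity)
  }
  activity
}

#' Initial curcumin mass in dosed medium
#'
#' Converts an extract dose to the curcumin mass it carries, using the
#' measured curcumin content of the extract (default 26.7 ug curcumin per
#' mg extract).
#'
#' @param extract_ug_ml Extract concentration, ug/mL.
#' @param volume_ml Medium volume, mL.
#' @param content_ug_per_mg Curcumin content of the extract, ug/mg.
#' @return Curcumin mass, ug.
#' @export
#' @examples
#' curcumin_mass(48.5)  # ~1.29 ug per mL of medium
curcumin_mass <- function(extract_ug_ml, volume_ml = 1,
                          content_ug_per_mg = 26.7) {
  assert_number(extract_ug_ml, "extract_ug_ml", positive = TRUE)
  assert_number(volume_ml, "volume_ml", positive = TRUE)
  assert_number(content_ug_per_mg, "content_ug_per_mg", positive = TRUE)
  extract_ug_ml * volume_ml * content_ug_per_mg / 1000
}
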