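#' Chou-Talalay combination index for one combination measurement
#'
#' For a combination `(d1, d2)` producing fraction affected `fa`, the
#' combination index is `CI = d1/Dx1(fa) + d2/Dx2(fa)`, where `Dx_i(fa)`
#' is the single-agent dose of agent i producing the same effect level
#' (from [dose_for_effect()]). `CI < 1` indicates synergy, `CI = 1`
#' additivity, `CI > 1` antagonism.
#'
#' A partner with no meaningful single-agent dose-response (see
#' [is_nontoxic()]) has `Dx2 -> Inf`; its term vanishes from the sum and
#' the result is flagged `partner_nontoxic`. This is the conservative
#' reading: `CI < 1` then still says the partner potentiates agent 1.
#'
#' @param d1,d2 Doses of agent 1 (TM) and agent 2 (BP), ug/mL; not both 0.
#' @param viability Measured viability of the combination, %. Alternatively
#'   supply `fa` directly.
#' @param fit1 Usable [fit_median_effect()] for agent 1.
#' @param fit2 [fit_median_effect()] for agent 2, or `NULL` when the
#'   partner has no dose-response.
#' @param fa Fraction affected; computed from `viability` when missing.
#' @param tol Half-width of the additivity band used for classification
#'   (default 0.05).
#' @param nontoxic_fa_threshold Passed to [is_nontoxic()] when deciding
#'   whether to drop the partner term.
#' @return One-row data frame of class `ci_result`: `tm_ug_ml`, `bp_ug_ml`,
#'   `fa`, `dx1`, `dx2` (`NA` for a non-toxic partner), `ci`,
#'   `classification`, `partner_nontoxic`.
#' @export
#' @examples
#' fit <- structure(list(m = 2, Dm = 77.8, usable = TRUE, max_fa = 0.9),
#'                  class = "median_effect_fit")
#' combination_index(d1 = 77.8, d2 = 0, viability = 50, fit1 = fit, fit2 = fit)
combination_index <- function(d1, d2, viability = NULL, fit1, fit2 = NULL,
                              fa = NULL, tol = 0.05,
                              nontoxic_fa_threshold = 0.2) {
  assert_number(d1, "d1"); assert_number(d2, "d2")
  if (d1 < 0 || d2 < 0) stopf("doses must be >= 0")
  if (d1 == 0 && d2 == 0) stopf("at least one dose must be > 0")
  stopifnot(inherits(fit1, "median_effect_fit"))
  if (!isTRUE(fit1$usable)) {
    stopf("combination index undefined: the primary agent's median-effect fit is unusable")
  }
  if (is.null(fa)) {
    if (is.null(viability)) stopf("supply either `viability` or `fa`")
    fa <- fraction_affected(viability)
  }
  if (fa <= 0 || fa >= 1) stopf("`fa` must lie in (0, 1)")

  dx1 <- dose_for_effect(fit1, fa)
  partner_nontoxic <- is.null(fit2) ||
    is_nontoxic(fit2, fa_threshold = nontoxic_fa_threshold)
  dx2 <- if (partner_nontoxic) NA_real_ else dose_for_effect(fit2, fa)
  ci <- d1 / dx1 + if (partner_nontoxic) 0 else d2 / dx2

  structure(
    data.frame(
      tm_ug_ml = d1, bp_ug_ml = d2, fa = fa,
      dx1 = dx1, dx2 = dx2, ci = ci,
      classification = classify_ci(ci, tol),
      partner_nontoxic = partner_nontoxic,
      stringsAsFactors = FALSE
    ),
    class = c("ci_result", "data.frame")
  )
}

#' Classify a combination index value
#'
#' Synergy when `ci < 1 - tol`, additive when `|ci - 1| <= tol`,
#' antagonism when `ci > 1 + tol`.
#'
#' @param ci Combination index value(s), >= 0.
#' @param tol Additivity half-width (default 0.05; CI software reports
#'   ranges rather than exact unity).
#' @return Character vector.
#' @export
classify_ci <- function(ci, tol = 0.05) {
  ifelse(ci < 1 - tol, "synergy",
         ifelse(ci > 1 + tol, "antagonism", "additive"))
}

#' Combination-index vs fraction-affected (CI-Fa) curve
#'
#' Computes one combination index per measurement and returns the results
#' sorted by fraction affected — the CI-Fa representation in which the
#' CI = 1 line separates synergy (below) from antagonism (above).
#'
#' @param measurements Data frame with columns `tm_ug_ml`, `bp_ug_ml` and
#'   `viability_pct` (or `fa`).
#' @param fit1,fit2 Median-effect fits for the two agents (`fit2` may be
#'   `NULL` for a non-toxic partner).
#' @param tol,nontoxic_fa_threshold Passed to [combination_index()].
#' @return Data frame of class `ci_fa_curve`, one row per measurement,
#'   sorted by `fa` ascending.
#' @export
ci_fa_curve <- function(measurements, fit1, fit2 = NULL, tol = 0.05,
                        nontoxic_fa_threshold = 0.2) {
  assert_columns(measurements, c("tm_ug_ml", "bp_ug_ml"), "measurements")
  if (nrow(measurements) < 1L) stopf("need >= 1 combination measurement")
  has_fa <- "fa" %in% names(measurements)
  if (!has_fa) {
    assert_columns(measurements, "viability_pct", "measurements")
  }
  rows <- lapply(seq_len(nrow(measurements)), function(i) {
    combination_index(
      d1 = measurements$tm_ug_ml[i],
      d2 = measurements$bp_ug_ml[i],
      viability = if (has_fa) NULL else measurements$viability_pct[i],
      fa = if (has_fa) measurements$fa[i] else NULL,
      fit1 = fit1, fit2 = fit2, tol = tol,
      nontoxic_fa_threshold = nontoxic_fa_threshold
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fa), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ci_fa_curve", "data.frame"))
}

#' Plot a CI-Fa curve
#'
#' Combination index against fraction affected with the CI = 1 additivity
#' reference line.
#'
#' @param x A [ci_fa_curve()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ci_fa_curve <- function(x, ...) {
  graphics::plot(x$fa, x$ci, xlab = "fraction affected (Fa)",
                 ylab = "combination index (CI)",
                 ylim = c(0, max(1.2, max(x$ci) * 1.1)),
                 pch = 19, ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
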