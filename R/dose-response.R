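#' Convert percent viability to fraction affected
#'
#' The combination-index machinery works on the fraction of cells affected,
#' `fa = 1 - viability/100`. Values are clamped to the open interval
#' `(eps, 1 - eps)` so the logit used by the median-effect fit stays
#' finite; clamping is part of the contract, not an error.
#'
#' @param viability Percent viability (finite; may exceed 100 or drop
#'   below 0 on real plates).
#' @param eps Clamp width (default 1e-4).
#' @return Fraction affected in `(eps, 1 - eps)`.
#' @export
#' @examples
#' fraction_affected(c(50, 100, 47.6))
fraction_affected <- function(viability, eps = 1e-4) {
  if (!all(is.finite(viability))) stopf("`viability` must be finite")
  pmin(pmax(1 - viability / 100, eps), 1 - eps)
}

#' Fit the median-effect dose-response model
#'
#' Chou's median-effect equation, `fa/fu = (D/Dm)^m`, is linear in log
#' space: `log10(fa/(1 - fa)) = m * log10(D) - m * log10(Dm)`. Replicates
#' are averaged per concentration, viability is transformed with
#' [fraction_affected()], and ordinary least squares of the logit on
#' `log10(D)` yields the slope `m` and the median-effect dose
#' `Dm = 10^(-intercept/m)` — the EC50 of the agent on that cell line.
#'
#' Averaged points whose mean viability is at or beyond the plate limits
#' (>= 100% or <= 0%) sit on the clamp and would enter the regression with
#' an arbitrary logit; they are excluded from the fit and counted in
#' `n_excluded`.
#'
#' @param table Data frame with columns `concentration_ug_ml` and
#'   `viability_pct` (plus optional `agent`, `cell_line`, `replicate`).
#' @param eps Clamp width passed to [fraction_affected()].
#' @return Object of class `median_effect_fit` with fields `m`, `Dm`, `r2`,
#'   `n_points`, `n_excluded`, `usable` (TRUE when `m > 0` and at least two
#'   usable points remain) and `max_fa` (largest mean fraction affected
#'   observed, used by [is_nontoxic()]).
#' @export
#' @examples
#' cfg <- generator_config(seed = 1, noise_cv = 0)
#' tab <- generate_single_agent_table(cfg, "TM", "A549",
#'                                    c(25, 50, 75, 100, 125, 150))
#' fit_median_effect(tab)
fit_median_effect <- function(table, eps = 1e-4) {
  assert_columns(table, c("concentration_ug_ml", "viability_pct"), "table")
  if (any(table$concentration_ug_ml <= 0)) {
    stopf("concentrations must be strictly positive")
  }
  if (!all(is.finite(table$viability_pct))) {
    stopf("viability values must be finite")
  }

  mean_viab <- tapply(table$viability_pct, table$concentration_ug_ml, mean)
  dose <- as.numeric(names(mean_viab))
  mean_viab <- as.numeric(mean_viab)
  if (length(dose) < 2L) {
    stopf("median-effect fit needs >= 2 distinct concentrations")
  }

  fa_all <- fraction_affected(mean_viab, eps = eps)
  usable_pt <- mean_viab < 100 & mean_viab > 0
  n_excluded <- sum(!usable_pt)
  dose_u <- dose[usable_pt]
  fa <- fa_all[usable_pt]
  if (length(dose_u) < 2L) {
    stopf("median-effect fit needs >= 2 usable points (off the viability clamp)")
  }
  x <- log10(dose_u)
  if (stats::sd(x) < 1e-12) stopf("zero variance in log10(dose)")
  y <- log10(fa / (1 - fa))

  ols <- stats::lm.fit(cbind(1, x), y)
  intercept <- ols$coefficients[[1]]
  m <- ols$coefficients[[2]]
  r2 <- safe_r2(y, y - ols$residuals)
  usable <- is.finite(m) && m > 0
  Dm <- if (usable) 10^(-intercept / m) else NA_real_

  structure(
    list(
      agent = if ("agent" %in% names(table)) table$agent[1] else NA_character_,
      cell_line = if ("cell_line" %in% names(table)) table$cell_line[1] else NA_character_,
      m = m,
      Dm = Dm,
      r2 = r2,
      n_points = length(dose_u),
      n_excluded = n_excluded,
      usable = usable,
      max_fa = max(fa_all)
    ),
    class = "median_effect_fit"
  )
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat("Median-effect fit",
      if (!is.na(x$agent)) paste0(" [", x$agent,
                                  if (!is.na(x$cell_line)) paste0(" on ", x$cell_line),
                                  "]"),
      "\n", sep = "")
  cat(sprintf("  m = %.4g, Dm (EC50) = %.4g ug/mL, r2 = %.4f\n",
              x$m, x$Dm, x$r2))
  cat(sprintf("  points used: %d (excluded on clamp: %d); usable: %s\n",
              x$n_points, x$n_excluded, x$usable))
  invisible(x)
}

#' Dose producing a given fraction affected
#'
#' Inverts the median-effect equation:
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`. Used both to read effect-level doses
#' off a single-agent fit and as the denominator of the combination index.
#'
#' @param fit A usable [fit_median_effect()] result.
#' @param fa Fraction(s) affected in (0, 1).
#' @return Dose(s), ug/mL.
#' @export
#' @examples
#' fit <- structure(list(m = 1, Dm = 50, usable = TRUE),
#'                  class = "median_effect_fit")
#' dose_for_effect(fit, 0.8)  # 200
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (!isTRUE(fit$usable)) {
    stopf("median-effect fit is not usable (non-positive slope or too few points)")
  }
  if (any(fa <= 0 | fa >= 1)) stopf("`fa` must lie in (0, 1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Is an agent effectively non-toxic over its tested range?
#'
#' A shallow-but-nonzero dose-response (like black pepper extract, < 10%
#' cell death at 400 ug/mL) can still yield a formally usable median-effect
#' line whose Dm lies far outside the tested range. For combination-index
#' purposes such a partner has no meaningful single-agent Dx and its CI
#' term is dropped. An agent is flagged non-toxic when its fit is unusable
#' or the largest mean fraction affected observed stays below
#' `fa_threshold`.
#'
#' @param fit A [fit_median_effect()] result.
#' @param fa_threshold Maximum observed fraction affected below which the
#'   agent counts as non-toxic (default 0.2).
#' @return Logical.
#' @export
is_nontoxic <- function(fit, fa_threshold = 0.2) {
  stopifnot(inherits(fit, "median_effect_fit"))
  !isTRUE(fit$usable) || fit$max_fa < fa_threshold
}

#' Summarize median-effect fits as a table
#'
#' @param fits List of [fit_median_effect()] results.
#' @return Data frame with columns `agent`, `cell_line`, `m`, `Dm`, `r2`,
#'   `usable`.
#' @export
median_effect_summary <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(agent = f$agent, cell_line = f$cell_line, m = f$m, Dm = f$Dm,
               r2 = f$r2, usable = f$usable, stringsAsFactors = FALSE)
  }))
}
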