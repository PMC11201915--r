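#' Build a two-factor central composite design
#'
#' Constructs the face-region CCD used for two-extract combination studies:
#' 4 factorial points at the second and fourth levels (coded +/-1), 4 axial
#' points at the extreme levels (coded +/-alpha with alpha = 2, so the
#' axial points land exactly on the stated extreme concentrations of a
#' uniformly spaced five-level grid), and `n_center` replicated center
#' points at the middle level (coded 0). With the default `n_center = 6`
#' the design has 14 runs.
#'
#' @param levels_tm,levels_bp Strictly increasing, uniformly spaced vectors
#'   of 5 concentrations (ug/mL) for the two factors.
#' @param n_center Number of center-point replicates (>= 2 so pure error is
#'   estimable).
#' @return Object of class `ccd_design`: list with `runs` (data frame
#'   `run`, `tm_coded`, `bp_coded`, `tm_ug_ml`, `bp_ug_ml`, `point_type`),
#'   `center`, `halfwidth` (natural-unit change per coded unit), `alpha`,
#'   `n_center` and `region` (natural-unit bounds).
#' @export
#' @examples
#' des <- build_ccd(seq(10, 50, 10), seq(200, 400, 50))
#' nrow(des$runs)  # 14
build_ccd <- function(levels_tm, levels_bp, n_center = 6L) {
  check_levels <- function(lv, name) {
    if (length(lv) != 5L) stopf("`%s` must have exactly 5 levels", name)
    d <- diff(lv)
    if (any(d <= 0)) stopf("`%s` must be strictly increasing", name)
    if (max(abs(d - d[1])) > 1e-8 * max(abs(lv))) {
      stopf("`%s` must be uniformly spaced (five equidistant levels)", name)
    }
    lv
  }
  levels_tm <- check_levels(levels_tm, "levels_tm")
  levels_bp <- check_levels(levels_bp, "levels_bp")
  if (n_center < 2L) stopf("`n_center` must be >= 2 for a pure-error estimate")

  alpha <- 2
  coded <- rbind(
    expand.grid(tm = c(-1, 1), bp = c(-1, 1)),                # factorial
    data.frame(tm = c(-alpha, alpha, 0, 0),
               bp = c(0, 0, -alpha, alpha)),                  # axial
    data.frame(tm = rep(0, n_center), bp = rep(0, n_center))  # center
  )
  point_type <- c(rep("factorial", 4L), rep("axial", 4L),
                  rep("center", n_center))
  center <- c(tm = levels_tm[3L], bp = levels_bp[3L])
  halfwidth <- c(tm = diff(levels_tm)[1L], bp = diff(levels_bp)[1L])

  runs <- data.frame(
    run = seq_len(nrow(coded)),
    tm_coded = coded$tm,
    bp_coded = coded$bp,
    tm_ug_ml = center[["tm"]] + halfwidth[["tm"]] * coded$tm,
    bp_ug_ml = center[["bp"]] + halfwidth[["bp"]] * coded$bp,
    point_type = point_type,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      runs = runs,
      center = center,
      halfwidth = halfwidth,
      alpha = alpha,
      n_center = as.integer(n_center),
      region = list(tm = range(levels_tm), bp = range(levels_bp))
    ),
    class = "ccd_design"
  )
}

#' @export
print.ccd_design <- function(x, ...) {
  cat(sprintf(
    "Central composite design: %d runs (4 factorial + 4 axial + %d center), alpha = %g\n",
    nrow(x$runs), x$n_center, x$alpha))
  cat(sprintf("  TM %g-%g ug/mL (center %g), BP %g-%g ug/mL (center %g)\n",
              x$region$tm[1], x$region$tm[2], x$center[["tm"]],
              x$region$bp[1], x$region$bp[2], x$center[["bp"]]))
  print(utils::head(x$runs, 8L))
  if (nrow(x$runs) > 8L) cat("  ...", nrow(x$runs) - 8L, "more center runs\n")
  invisible(x)
}

# Convert coded-unit quadratic coefficients to natural units by expanding
# x = (z - c) / h into Y = b0 + b1 x1 + b2 x2 + b11 x1^2 + b22 x2^2 + b12 x1 x2.
coded_to_natural <- function(b, center, halfwidth) {
  g1 <- 1 / halfwidth[["tm"]]; g2 <- 1 / halfwidth[["bp"]]
  a1 <- -center[["tm"]] * g1;  a2 <- -center[["bp"]] * g2
  c(
    b0 = unname(b[1] + b[2] * a1 + b[3] * a2 + b[4] * a1^2 + b[5] * a2^2 +
                  b[6] * a1 * a2),
    b_tm = unname(b[2] * g1 + 2 * b[4] * g1 * a1 + b[6] * g1 * a2),
    b_bp = unname(b[3] * g2 + 2 * b[5] * g2 * a2 + b[6] * g2 * a1),
    b_tm2 = unname(b[4] * g1^2),
    b_bp2 = unname(b[5] * g2^2),
    b_tmbp = unname(b[6] * g1 * g2)
  )
}

#' Fit the quadratic response-surface model
#'
#' Least-squares fit of
#' `Y = b0 + b1*TM + b2*BP + b11*TM^2 + b22*BP^2 + b12*TM*BP`
#' (viability %, concentrations in ug/mL) to combination responses,
#' performed internally in coded units for conditioning and reported in
#' both scales. Diagnostics follow response-surface practice: the residual
#' sum of squares is split into lack-of-fit and pure error over replicated
#' design points, with `F_lof = (SS_lof/df_lof) / (SS_pe/df_pe)`; adequate
#' precision is the predicted-response range at the design points divided
#' by `sqrt(p * MSE / n)` (p = 6 parameters, n = runs); the coefficient of
#' variation is `100 * sqrt(MSE) / mean(Y)`.
#'
#' @param design A [build_ccd()] design (supplies the coding and region).
#' @param responses Data frame with columns `tm_ug_ml`, `bp_ug_ml`,
#'   `viability_pct` (e.g. one cell line's rows from
#'   [generate_ccd_response_table()]). Needs >= 6 distinct design points
#'   and >= 2 replicates somewhere for pure error.
#' @param response_name Label for the response (cell line); taken from a
#'   `cell_line` column when present.
#' @return Object of class `rsm_fit`: coefficients `beta` (natural units)
#'   and `beta_coded`, `anova` table (model / residual / lack-of-fit /
#'   pure-error SS and df), `r2`, `adj_r2`, `adeq_precision`, `cv_pct`,
#'   `lof_f`, `lof_p`, plus the design `region` used by [predict.rsm_fit()].
#' @export
fit_quadratic <- function(design, responses, response_name = NULL) {
  stopifnot(inherits(design, "ccd_design"))
  assert_columns(responses, c("tm_ug_ml", "bp_ug_ml", "viability_pct"),
                 "responses")
  if (is.null(response_name)) {
    response_name <- if ("cell_line" %in% names(responses)) {
      as.character(responses$cell_line[1])
    } else "response"
  }
  tm <- responses$tm_ug_ml
  bp <- responses$bp_ug_ml
  y <- responses$viability_pct
  n <- length(y)
  key <- paste(signif(tm, 12), signif(bp, 12))
  if (length(unique(key)) < 6L) {
    stopf("quadratic fit needs >= 6 distinct design points")
  }
  if (max(table(key)) < 2L) {
    stopf("pure error needs >= 2 replicates at some design point")
  }

  # coded model matrix
  x1 <- (tm - design$center[["tm"]]) / design$halfwidth[["tm"]]
  x2 <- (bp - design$center[["bp"]]) / design$halfwidth[["bp"]]
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2,
             `x1^2` = x1^2, `x2^2` = x2^2, `x1:x2` = x1 * x2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("model matrix is rank-deficient; aliased term(s): %s",
          paste(aliased, collapse = ", "))
  }
  beta_coded <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta_coded)
  resid <- y - fitted

  ss_total <- sum((y - mean(y))^2)
  ss_resid <- sum(resid^2)
  ss_model <- ss_total - ss_resid
  # pure error: replicate spread within identical design points
  ss_pe <- sum(unlist(tapply(y, key, function(v) sum((v - mean(v))^2))))
  df_pe <- n - length(unique(key))
  ss_lof <- max(ss_resid - ss_pe, 0)
  p <- ncol(X)
  df_model <- p - 1L
  df_resid <- n - p
  df_lof <- df_resid - df_pe
  mse <- ss_resid / df_resid
  r2 <- safe_r2(y, fitted)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_resid
  lof_f <- if (df_lof > 0 && ss_pe > 0) {
    (ss_lof / df_lof) / (ss_pe / df_pe)
  } else NA_real_
  lof_p <- if (is.finite(lof_f)) {
    stats::pf(lof_f, df_lof, df_pe, lower.tail = FALSE)
  } else NA_real_
  adeq_precision <- (max(fitted) - min(fitted)) / sqrt(p * mse / n)
  cv_pct <- 100 * sqrt(mse) / mean(y)

  anova_tab <- data.frame(
    source = c("model", "residual", "lack_of_fit", "pure_error", "total"),
    ss = c(ss_model, ss_resid, ss_lof, ss_pe, ss_total),
    df = c(df_model, df_resid, df_lof, df_pe, n - 1L),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      response_name = response_name,
      beta = coded_to_natural(beta_coded, design$center, design$halfwidth),
      beta_coded = beta_coded,
      center = design$center,
      halfwidth = design$halfwidth,
      anova = anova_tab,
      r2 = r2,
      adj_r2 = adj_r2,
      lof_f = lof_f,
      lof_p = lof_p,
      adeq_precision = adeq_precision,
      cv_pct = cv_pct,
      mse = mse,
      n = n,
      region = design$region
    ),
    class = "rsm_fit"
  )
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat("Quadratic response-surface fit:", x$response_name, "\n")
  cat("  natural-unit coefficients (viability % over TM, BP ug/mL):\n")
  print(signif(x$beta, 6))
  cat(sprintf("  R2 = %.4f, adj R2 = %.4f, CV = %.2f%%, Adeq Precision = %.2f\n",
              x$r2, x$adj_r2, x$cv_pct, x$adeq_precision))
  if (is.finite(x$lof_f)) {
    cat(sprintf("  lack-of-fit F = %.3f (p = %.3g)\n", x$lof_f, x$lof_p))
  }
  invisible(x)
}

#' Predict viability from a fitted response surface
#'
#' Evaluates the quadratic surface at the supplied concentrations. Points
#' up to 5% (of each factor's span) beyond the design region trigger a
#' warning; points further out are an error, since a quadratic fitted on
#' the design region says nothing trustworthy there.
#'
#' @param object An [fit_quadratic()] result.
#' @param tm,bp Concentrations, ug/mL (vectorized, recycled to a common
#'   length).
#' @param ... Unused.
#' @return Predicted viability, %.
#' @export
predict.rsm_fit <- function(object, tm, bp, ...) {
  k <- max(length(tm), length(bp))
  tm <- rep_len(tm, k); bp <- rep_len(bp, k)
  check_axis <- function(v, rng, label) {
    span <- diff(rng)
    excess <- pmax(rng[1] - v, v - rng[2], 0) / span
    if (any(excess > 0.05)) {
      stopf("%s = %.4g ug/mL is > 5%% beyond the design region [%g, %g]",
            label, v[which.max(excess)], rng[1], rng[2])
    }
    if (any(excess > 0)) {
      warnf("mild extrapolation: %s outside the design region [%g, %g]",
            label, rng[1], rng[2])
    }
  }
  check_axis(tm, object$region$tm, "tm")
  check_axis(bp, object$region$bp, "bp")
  eval_quadratic(unname(object$beta), tm, bp)
}
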