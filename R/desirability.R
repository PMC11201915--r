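#' Define a desirability goal for one response
#'
#' Derringer-style goals: hit a target `T` within bounds `[L, U]`, maximize
#' toward `U`, or minimize toward `L`. Exponents `s` and `t` shape the
#' rising and falling ramps (1 = linear).
#'
#' @param response_name Response (cell line) the goal applies to.
#' @param kind `"target"`, `"maximize"` or `"minimize"`.
#' @param target Target value (required for `"target"`).
#' @param low,high Lower/upper acceptability bounds (% viability).
#' @param s,t Positive ramp exponents.
#' @return Object of class `desirability_goal`.
#' @export
desirability_goal <- function(response_name,
                              kind = c("target", "maximize", "minimize"),
                              target = NA_real_, low, high, s = 1, t = 1) {
  kind <- match.arg(kind)
  assert_number(low, "low"); assert_number(high, "high")
  if (low >= high) stopf("`low` must be < `high`")
  if (s <= 0 || t <= 0) stopf("ramp exponents `s`, `t` must be > 0")
  if (kind == "target") {
    assert_number(target, "target")
    if (!(low < target && target < high)) {
      stopf("target goals need low < target < high")
    }
  }
  structure(
    list(response_name = response_name, kind = kind, target = target,
         low = low, high = high, s = s, t = t),
    class = "desirability_goal"
  )
}

#' Per-response desirability transform
#'
#' Maps a predicted response to `[0, 1]`. For a target goal:
#' `d = ((y - L)/(T - L))^s` on the rising side, `((U - y)/(U - T))^t` on
#' the falling side, 0 outside `[L, U]`, and `d = 1` exactly at `y = T`.
#'
#' @param y Predicted response value(s), % viability.
#' @param goal A [desirability_goal()].
#' @return Desirability value(s) in `[0, 1]`.
#' @export
#' @examples
#' g <- desirability_goal("A549", "target", target = 50, low = 0, high = 100)
#' desirability_score(c(50, 0, 53.3), g)
desirability_score <- function(y, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  L <- goal$low; U <- goal$high
  d <- numeric(length(y))
  if (goal$kind == "target") {
    Tt <- goal$target
    rising <- y >= L & y <= Tt
    falling <- y > Tt & y <= U
    d[rising] <- ((y[rising] - L) / (Tt - L))^goal$s
    d[falling] <- ((U - y[falling]) / (U - Tt))^goal$t
  } else if (goal$kind == "maximize") {
    mid <- y > L & y < U
    d[y >= U] <- 1
    d[mid] <- ((y[mid] - L) / (U - L))^goal$s
  } else {
    mid <- y > L & y < U
    d[y <= L] <- 1
    d[mid] <- ((U - y[mid]) / (U - L))^goal$t
  }
  pmin(pmax(d, 0), 1)
}

#' Overall desirability (geometric mean)
#'
#' `D = (d1 * d2 * ... * dn)^(1/n)`; any single unacceptable response
#' (`d = 0`) annihilates the combination.
#'
#' @param d_values Numeric vector of per-response desirabilities in
#'   `[0, 1]`.
#' @return Overall desirability in `[0, 1]`.
#' @export
#' @examples
#' overall_desirability(c(1, 1))      # 1
#' overall_desirability(c(0.25, 1))   # 0.5
overall_desirability <- function(d_values) {
  if (length(d_values) == 0L) stopf("`d_values` must be non-empty")
  if (any(!is.finite(d_values)) || any(d_values < 0 | d_values > 1)) {
    stopf("desirabilities must lie in [0, 1]")
  }
  if (any(d_values == 0)) return(0)
  exp(mean(log(d_values)))
}

#' Data-driven bounds for a target goal
#'
#' Design-Expert's default acceptability window for a response is the range
#' it can reach: the min/max predicted value over the design region,
#' evaluated here on a fine grid.
#'
#' @param fit An [fit_quadratic()] result.
#' @param region List with `tm` and `bp` range vectors; defaults to the
#'   fit's design region.
#' @param grid_n Grid points per axis.
#' @return Numeric `c(low, high)`.
#' @export
predicted_response_bounds <- function(fit, region = fit$region, grid_n = 201L) {
  tm <- seq(region$tm[1], region$tm[2], length.out = grid_n)
  bp <- seq(region$bp[1], region$bp[2], length.out = grid_n)
  g <- expand.grid(tm = tm, bp = bp)
  y <- eval_quadratic(unname(fit$beta), g$tm, g$bp)
  c(low = min(y), high = max(y))
}

# Overall desirability at (tm, bp) given fitted surfaces and goals.
eval_overall_d <- function(tm, bp, fits, goals) {
  d <- vapply(seq_along(fits), function(i) {
    y <- eval_quadratic(unname(fits[[i]]$beta), tm, bp)
    desirability_score(y, goals[[i]])
  }, numeric(length(tm)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
  apply(d, 1L, function(row) if (any(row == 0)) 0 else exp(mean(log(row))))
}

#' Search the concentration region for optimal combinations
#'
#' Ranks candidate (TM, BP) combinations by overall desirability. The
#' search is a dense grid pass (`grid_n` per axis) followed by Nelder-Mead
#' polish from each grid-local optimum; when every goal is a target goal,
#' the best candidates get an extra Gauss-Newton-style polish that drives
#' all predicted responses onto their targets exactly (where the target
#' contours intersect inside the region), so an attainable `D = 1` optimum
#' is reported as exactly 1. Solutions closer than `dedup_frac` of each
#' factor's span are merged; ties in D are broken toward the lower total
#' concentration (pharmacological parsimony).
#'
#' @param fits List of [fit_quadratic()] results (one per response).
#' @param goals List of [desirability_goal()], parallel to `fits`.
#' @param region List with `tm`, `bp` concentration bounds; defaults to the
#'   first fit's design region.
#' @param k Number of ranked solutions to return.
#' @param grid_n First-pass grid resolution per axis.
#' @param dedup_frac Deduplication resolution as a fraction of each
#'   factor's span (default 0.005 = 0.5%).
#' @return Object of class `desirability_solutions`: data frame with
#'   columns `rank`, `desirability`, `tm_ug_ml`, `bp_ug_ml`, one
#'   `pred_<response>` and one `d_<response>` column per response.
#' @export
optimize_desirability <- function(fits, goals, region = fits[[1]]$region,
                                  k = 5L, grid_n = 201L, dedup_frac = 0.005) {
  if (length(fits) != length(goals)) {
    stopf("need exactly one goal per fitted response")
  }
  tm_grid <- seq(region$tm[1], region$tm[2], length.out = grid_n)
  bp_grid <- seq(region$bp[1], region$bp[2], length.out = grid_n)
  g <- expand.grid(tm = tm_grid, bp = bp_grid)
  D <- eval_overall_d(g$tm, g$bp, fits, goals)
  if (all(D == 0)) {
    warnf("desirability is zero everywhere in the region; no solutions")
    return(empty_solutions(fits))
  }

  Dm <- matrix(D, nrow = grid_n, ncol = grid_n)
  # grid-local maxima: cells not dominated by any 8-neighbour
  shift <- function(M, di, dj) {
    out <- matrix(-Inf, nrow(M), ncol(M))
    ri <- seq_len(nrow(M)) + di; rj <- seq_len(ncol(M)) + dj
    ok_i <- ri >= 1 & ri <= nrow(M); ok_j <- rj >= 1 & rj <= ncol(M)
    out[ok_i, ok_j] <- M[ri[ok_i], rj[ok_j]]
    out
  }
  nbr_max <- Reduce(pmax, lapply(
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1)),
    function(s) shift(Dm, s[1], s[2])
  ))
  is_peak <- Dm >= nbr_max & Dm > 0
  peaks <- which(is_peak, arr.ind = TRUE)
  cand <- data.frame(tm = tm_grid[peaks[, 1]], bp = bp_grid[peaks[, 2]],
                     D = Dm[peaks])
  cand <- cand[order(-cand$D), , drop = FALSE]
  cand <- utils::head(cand, max(10L * k, 40L))

  clamp_region <- function(par) {
    c(min(max(par[1], region$tm[1]), region$tm[2]),
      min(max(par[2], region$bp[1]), region$bp[2]))
  }
  neg_d <- function(par) {
    p <- clamp_region(par)
    -eval_overall_d(p[1], p[2], fits, goals)
  }
  all_targets <- all(vapply(goals, function(g) g$kind == "target", logical(1)))

  polished <- lapply(seq_len(nrow(cand)), function(i) {
    start <- c(cand$tm[i], cand$bp[i])
    opt <- stats::optim(start, neg_d, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    par <- clamp_region(opt$par)
    if (all_targets && length(fits) == 2L) {
      rp <- newton_target_polish(par, fits, goals, region)
      if (!is.null(rp) &&
          eval_overall_d(rp[1], rp[2], fits, goals) >=
            eval_overall_d(par[1], par[2], fits, goals)) {
        par <- rp
      }
    }
    c(par, eval_overall_d(par[1], par[2], fits, goals))
  })
  sol <- do.call(rbind, polished)
  sol <- data.frame(tm = sol[, 1], bp = sol[, 2], D = sol[, 3])

  # dedupe at the stated concentration resolution
  res_tm <- dedup_frac * diff(region$tm)
  res_bp <- dedup_frac * diff(region$bp)
  keykey <- paste(round(sol$tm / res_tm), round(sol$bp / res_bp))
  sol <- sol[!duplicated(keykey), , drop = FALSE]

  # rank by D descending; ties toward the lower total concentration
  sol <- sol[order(-sol$D, sol$tm + sol$bp), , drop = FALSE]
  sol <- utils::head(sol, k)

  out <- data.frame(
    rank = seq_len(nrow(sol)),
    desirability = sol$D,
    tm_ug_ml = sol$tm,
    bp_ug_ml = sol$bp
  )
  for (i in seq_along(fits)) {
    nm <- fits[[i]]$response_name
    pred <- eval_quadratic(unname(fits[[i]]$beta), sol$tm, sol$bp)
    out[[paste0("pred_", nm)]] <- pred
    out[[paste0("d_", nm)]] <- desirability_score(pred, goals[[i]])
  }
  structure(out, class = c("desirability_solutions", "data.frame"))
}

# Newton iteration on the 2x2 system (Y1(tm,bp) - T1, Y2(tm,bp) - T2) = 0.
# Returns the in-region root near `start` (where the two target contours
# intersect, the overall desirability is exactly 1), or NULL if the
# iteration leaves the region or fails to converge.
newton_target_polish <- function(start, fits, goals, region,
                                 max_iter = 40L, tol = 1e-12) {
  b1 <- unname(fits[[1]]$beta); b2 <- unname(fits[[2]]$beta)
  p <- start
  for (i in seq_len(max_iter)) {
    f <- c(eval_quadratic(b1, p[1], p[2]) - goals[[1]]$target,
           eval_quadratic(b2, p[1], p[2]) - goals[[2]]$target)
    if (max(abs(f)) < tol) break
    J <- rbind(
      c(b1[2] + 2 * b1[4] * p[1] + b1[6] * p[2],
        b1[3] + 2 * b1[5] * p[2] + b1[6] * p[1]),
      c(b2[2] + 2 * b2[4] * p[1] + b2[6] * p[2],
        b2[3] + 2 * b2[5] * p[2] + b2[6] * p[1])
    )
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    p <- p - step
  }
  f <- c(eval_quadratic(b1, p[1], p[2]) - goals[[1]]$target,
         eval_quadratic(b2, p[1], p[2]) - goals[[2]]$target)
  in_region <- p[1] >= region$tm[1] && p[1] <= region$tm[2] &&
    p[2] >= region$bp[1] && p[2] <= region$bp[2]
  if (max(abs(f)) < tol && in_region) p else NULL
}

empty_solutions <- function(fits) {
  out <- data.frame(rank = integer(), desirability = numeric(),
                    tm_ug_ml = numeric(), bp_ug_ml = numeric())
  for (f in fits) {
    out[[paste0("pred_", f$response_name)]] <- numeric()
    out[[paste0("d_", f$response_name)]] <- numeric()
  }
  structure(out, class = c("desirability_solutions", "data.frame"))
}

#' @export
print.desirability_solutions <- function(x, ...) {
  cat("Ranked optimal combinations (overall desirability, Eq.-style geometric mean)\n")
  print.data.frame(
    cbind(x["rank"],
          desirability = signif(x$desirability, 4),
          tm_ug_ml = signif(x$tm_ug_ml, 4),
          bp_ug_ml = signif(x$bp_ug_ml, 4),
          signif(x[setdiff(names(x),
                           c("rank", "desirability", "tm_ug_ml", "bp_ug_ml"))],
                 4)),
    row.names = FALSE)
  invisible(x)
}
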