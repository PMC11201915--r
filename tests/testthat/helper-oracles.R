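# Independent oracles used to cross-check the package's estimators.

# Zooming grid search over (m, Dm) minimizing the summed squared logit
# residuals — the same least-squares criterion the median-effect fit
# minimizes, located without any regression machinery.
grid_search_median_effect <- function(dose, viability,
                                      m_range = c(0.1, 10),
                                      dm_range = NULL,
                                      n_grid = 25L, n_zoom = 18L) {
  mean_viab <- tapply(viability, dose, mean)
  d <- as.numeric(names(mean_viab))
  fa <- pmin(pmax(1 - as.numeric(mean_viab) / 100, 1e-4), 1 - 1e-4)
  keep <- as.numeric(mean_viab) < 100 & as.numeric(mean_viab) > 0
  d <- d[keep]; fa <- fa[keep]
  x <- log10(d)
  y <- log10(fa / (1 - fa))
  if (is.null(dm_range)) dm_range <- c(min(d) / 10, max(d) * 10)
  lo <- c(m_range[1], log10(dm_range[1]))
  hi <- c(m_range[2], log10(dm_range[2]))
  best <- NULL
  for (it in seq_len(n_zoom)) {
    ms <- seq(lo[1], hi[1], length.out = n_grid)
    lds <- seq(lo[2], hi[2], length.out = n_grid)
    g <- expand.grid(m = ms, ld = lds)
    sse <- vapply(seq_len(nrow(g)), function(i) {
      sum((y - g$m[i] * (x - g$ld[i]))^2)
    }, numeric(1))
    best <- g[which.min(sse), ]
    span <- c(ms[2] - ms[1], lds[2] - lds[1])
    lo <- c(best$m - 2 * span[1], best$ld - 2 * span[2])
    hi <- c(best$m + 2 * span[1], best$ld + 2 * span[2])
  }
  list(m = best$m, Dm = 10^best$ld)
}

# Normal-equations solution of the coded quadratic least-squares problem.
normal_equations_quadratic <- function(design, responses) {
  x1 <- (responses$tm_ug_ml - design$center[["tm"]]) / design$halfwidth[["tm"]]
  x2 <- (responses$bp_ug_ml - design$center[["bp"]]) / design$halfwidth[["bp"]]
  X <- cbind(1, x1, x2, x1^2, x2^2, x1 * x2)
  drop(solve(crossprod(X), crossprod(X, responses$viability_pct)))
}

# Two-point finite-difference slope of a noiseless linear series.
finite_difference_slope <- function(time, value) {
  i <- which.min(time); j <- which.max(time)
  (value[j] - value[i]) / (time[j] - time[i])
}

# Exhaustive grid evaluation of overall desirability (target goals).
grid_oracle_best_d <- function(fits, goals, region, n = 2000L) {
  tm <- seq(region$tm[1], region$tm[2], length.out = n)
  bp <- seq(region$bp[1], region$bp[2], length.out = n)
  best <- 0
  # evaluate in bp-slices to bound memory
  for (b in bp) {
    d_all <- rep(1, length(tm))
    zero <- rep(FALSE, length(tm))
    logsum <- rep(0, length(tm))
    for (i in seq_along(fits)) {
      beta <- unname(fits[[i]]$beta)
      y <- beta[1] + beta[2] * tm + beta[3] * b + beta[4] * tm^2 +
        beta[5] * b^2 + beta[6] * tm * b
      di <- desirability_score(y, goals[[i]])
      zero <- zero | di == 0
      logsum <- logsum + ifelse(di > 0, log(di), 0)
    }
    D <- ifelse(zero, 0, exp(logsum / length(fits)))
    best <- max(best, max(D))
  }
  best
}

# Small noiseless generator config shared across tests.
noiseless_config <- function(seed = 1L) {
  generator_config(seed = seed, noise_cv = 0)
}

paper_levels_tm <- function() seq(10, 50, by = 10)
paper_levels_bp <- function() seq(200, 400, by = 50)
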