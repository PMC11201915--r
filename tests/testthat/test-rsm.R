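test_that("five uniformly spaced levels per factor yield the 14-run CCD", {
  des <- build_ccd(paper_levels_tm(), paper_levels_bp(), n_center = 6)
  expect_equal(nrow(des$runs), 14L)
  expect_equal(sum(des$runs$point_type == "factorial"), 4L)
  expect_equal(sum(des$runs$point_type == "axial"), 4L)
  expect_equal(sum(des$runs$point_type == "center"), 6L)
  # design symmetry: coded column means are zero
  expect_equal(mean(des$runs$tm_coded), 0)
  expect_equal(mean(des$runs$bp_coded), 0)
  # natural center and extremes
  center <- des$runs[des$runs$point_type == "center", ][1, ]
  expect_equal(c(center$tm_ug_ml, center$bp_ug_ml), c(30, 300))
  expect_setequal(unique(des$runs$tm_ug_ml), c(10, 20, 30, 40, 50))
  expect_setequal(unique(des$runs$bp_ug_ml), c(200, 250, 300, 350, 400))
  # axial distance alpha = 2 puts star points on the extreme levels
  expect_equal(des$alpha, 2)
  expect_setequal(des$runs$tm_coded[des$runs$point_type == "axial"],
                  c(-2, 2, 0))
})

test_that("degenerate level grids are rejected", {
  expect_error(build_ccd(c(10, 20, 35, 40, 50), paper_levels_bp()),
               "uniformly spaced")
  expect_error(build_ccd(c(10, 20, 30, 40), paper_levels_bp()), "5 levels")
  expect_error(build_ccd(c(50, 40, 30, 20, 10), paper_levels_bp()),
               "increasing")
  expect_error(build_ccd(paper_levels_tm(), paper_levels_bp(), n_center = 1),
               "pure-error")
})

test_that("quadratic fit matches the independent normal-equations solution", {
  cfg <- generator_config(seed = 31, noise_cv = 0.05)
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  tab <- generate_ccd_response_table(cfg, des, responses = "A549")
  fit <- fit_quadratic(des, tab)
  oracle <- normal_equations_quadratic(des, tab)
  expect_equal(unname(fit$beta_coded), unname(oracle), tolerance = 1e-8)
})

test_that("ANOVA decomposition satisfies its identities", {
  cfg <- generator_config(seed = 13, noise_cv = 0.06)
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  tab <- generate_ccd_response_table(cfg, des, responses = "NCI-H292")
  fit <- fit_quadratic(des, tab)
  a <- fit$anova
  ss <- function(src) a$ss[a$source == src]
  df <- function(src) a$df[a$source == src]
  expect_equal(ss("residual"), ss("lack_of_fit") + ss("pure_error"),
               tolerance = 1e-8 * ss("total"))
  expect_equal(ss("total"), ss("model") + ss("lack_of_fit") + ss("pure_error"),
               tolerance = 1e-8 * ss("total"))
  expect_true(all(a$df >= 0))
  expect_equal(df("total"), df("model") + df("residual"))
  expect_lte(fit$adj_r2, fit$r2)
  expect_gte(fit$cv_pct, 0)
  expect_gte(fit$adeq_precision, 0)
})

test_that("dropping the interaction term cannot decrease the residual SS", {
  cfg <- generator_config(seed = 5, noise_cv = 0.05)
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  tab <- generate_ccd_response_table(cfg, des, responses = "A549")
  x1 <- (tab$tm_ug_ml - 30) / 10
  x2 <- (tab$bp_ug_ml - 300) / 50
  full <- stats::lm(viability_pct ~ x1 + x2 + I(x1^2) + I(x2^2) + x1:x2,
                    data = tab)
  reduced <- stats::lm(viability_pct ~ x1 + x2 + I(x1^2) + I(x2^2),
                       data = tab)
  expect_gte(sum(stats::residuals(reduced)^2), sum(stats::residuals(full)^2))
})

test_that("coded-space and natural-space coefficients predict identically", {
  cfg <- generator_config(seed = 9, noise_cv = 0.04)
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  tab <- generate_ccd_response_table(cfg, des, responses = "A549")
  fit <- fit_quadratic(des, tab)
  pts <- des$runs
  x1 <- pts$tm_coded; x2 <- pts$bp_coded
  coded_pred <- drop(cbind(1, x1, x2, x1^2, x2^2, x1 * x2) %*% fit$beta_coded)
  natural_pred <- predict(fit, pts$tm_ug_ml, pts$bp_ug_ml)
  expect_equal(natural_pred, coded_pred, tolerance = 1e-9)
})

test_that("rank deficiency is reported with the aliased term", {
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  # responses only at a single bp level: bp, bp^2 and the intercept alias
  tab <- data.frame(
    tm_ug_ml = c(10, 20, 30, 30, 40, 50, 25, 35),
    bp_ug_ml = 300,
    viability_pct = c(90, 80, 70, 71, 60, 50, 75, 65)
  )
  expect_error(fit_quadratic(des, tab), "aliased")
})

test_that("prediction guards the design region", {
  cfg <- noiseless_config()
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  tab <- generate_ccd_response_table(cfg, des, responses = "A549")
  fit <- fit_quadratic(des, tab)
  expect_silent(p <- predict(fit, 48.5, 241.7))
  expect_equal(p, 50, tolerance = 1e-6)
  expect_warning(predict(fit, 51, 300), "extrapolation")   # within 5%
  expect_error(predict(fit, 60, 300), "beyond the design region")
  # constant surface predicts its constant
  const <- fit
  const$beta <- c(b0 = 100, b_tm = 0, b_bp = 0, b_tm2 = 0, b_bp2 = 0,
                  b_tmbp = 0)
  expect_equal(predict(const, c(10, 30, 50), c(200, 300, 400)),
               rep(100, 3))
})

test_that("coefficient estimates are unbiased under replicate noise", {
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  truth <- default_surface_coeffs()[["A549"]]
  est <- matrix(NA_real_, nrow = 500, ncol = 6)
  for (s in 1:500) {
    cfg <- generator_config(seed = 1000 + s, noise_cv = 0.05)
    tab <- generate_ccd_response_table(cfg, des, responses = "A549")
    est[s, ] <- fit_quadratic(des, tab)$beta
  }
  bias <- colMeans(est) - unname(truth)
  mc_se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_true(all(abs(bias) <= pmax(0.02 * abs(unname(truth)), 4 * mc_se)))
})
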