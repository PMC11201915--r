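target_goal <- function(name = "A549", target = 50, low = 0, high = 100,
                        s = 1, t = 1) {
  desirability_goal(name, "target", target = target, low = low, high = high,
                    s = s, t = t)
}

test_that("target desirability transform follows the two-sided ramp", {
  g <- target_goal()
  expect_equal(desirability_score(50, g), 1)          # on target
  expect_equal(desirability_score(c(0, 100), g), c(0, 0))  # at the bounds
  expect_equal(desirability_score(53.3, g), (100 - 53.3) / 50)  # 0.934
  expect_equal(desirability_score(25, g), 0.5)
  # outside the acceptability window
  expect_equal(desirability_score(c(-10, 130), g), c(0, 0))
  # d = 1 iff y = T
  ys <- seq(1, 99, by = 0.5)
  d <- desirability_score(ys, g)
  expect_identical(ys[d == 1], 50)
  # ramp exponents bend the ramps
  g2 <- target_goal(s = 2, t = 0.5)
  expect_equal(desirability_score(25, g2), 0.25)
  expect_equal(desirability_score(75, g2), sqrt(0.5))
})

test_that("maximize and minimize goals ramp toward their bound", {
  gmax <- desirability_goal("r", "maximize", low = 0, high = 100)
  expect_equal(desirability_score(c(-5, 0, 50, 100, 120), gmax),
               c(0, 0, 0.5, 1, 1))
  gmin <- desirability_goal("r", "minimize", low = 0, high = 100)
  expect_equal(desirability_score(c(-5, 0, 50, 100, 120), gmin),
               c(1, 1, 0.5, 0, 0))
})

test_that("goal constructor validates bounds and exponents", {
  expect_error(desirability_goal("r", "target", target = 50, low = 60,
                                 high = 100), "low < target < high")
  expect_error(desirability_goal("r", "target", target = 50, low = 0,
                                 high = 40), "low < target < high")
  expect_error(desirability_goal("r", "maximize", low = 10, high = 10),
               "`low` must be < `high`")
  expect_error(target_goal(s = 0), "> 0")
})

test_that("overall desirability is the geometric mean with annihilation", {
  expect_equal(overall_desirability(c(1, 1)), 1)
  expect_equal(overall_desirability(c(1, 0)), 0)
  expect_equal(overall_desirability(c(0.25, 1)), 0.5)
  expect_error(overall_desirability(numeric(0)), "non-empty")
  expect_error(overall_desirability(c(0.5, 1.2)), "\\[0, 1\\]")
  # order invariance
  d <- c(0.3, 0.8, 0.6)
  expect_equal(overall_desirability(d), overall_desirability(rev(d)))
  # geometric-mean homogeneity: scaling all d_i by c scales D by c
  for (c_scale in c(0.2, 0.5, 0.9)) {
    expect_equal(overall_desirability(c_scale * d),
                 c_scale * overall_desirability(d), tolerance = 1e-12)
  }
})

fitted_default_surfaces <- function() {
  cfg <- noiseless_config()
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  tab <- generate_ccd_response_table(cfg, des)
  lapply(names(cfg$surface_coeffs), function(cl) {
    fit_quadratic(des, tab[tab$cell_line == cl, ], response_name = cl)
  })
}

default_target_goals <- function(fits, target = 50) {
  lapply(fits, function(f) {
    b <- predicted_response_bounds(f)
    desirability_goal(f$response_name, "target", target = target,
                      low = b[["low"]], high = b[["high"]])
  })
}

test_that("optimizer finds the interior point where both responses hit 50%", {
  fits <- fitted_default_surfaces()
  goals <- default_target_goals(fits)
  sol <- optimize_desirability(fits, goals, k = 5)
  expect_equal(sol$desirability[1], 1, tolerance = 1e-9)
  expect_equal(sol$tm_ug_ml[1], 48.5, tolerance = 1e-6)
  expect_equal(sol$bp_ug_ml[1], 241.7, tolerance = 1e-6)
  expect_equal(sol[[1, "pred_A549"]], 50, tolerance = 1e-9)
  expect_equal(sol[[1, "pred_NCI-H292"]], 50, tolerance = 1e-9)
  # overall D is the geometric mean of the reported per-response d_i
  for (i in seq_len(nrow(sol))) {
    expect_equal(sol$desirability[i],
                 overall_desirability(c(sol[[i, "d_A549"]],
                                        sol[[i, "d_NCI-H292"]])),
                 tolerance = 1e-12)
  }
  # ranked column is monotone non-increasing
  expect_true(all(diff(sol$desirability) <= 1e-12))
})

test_that("optimizer is at least as good as an exhaustive fine-grid oracle", {
  fits <- fitted_default_surfaces()
  goals <- default_target_goals(fits)
  sol <- optimize_desirability(fits, goals, k = 1)
  oracle <- grid_oracle_best_d(fits, goals, fits[[1]]$region, n = 2000)
  expect_gte(sol$desirability[1], oracle - 1e-6)
})

test_that("an all-zero desirability region yields an empty result with a warning", {
  fits <- fitted_default_surfaces()
  # target far above anything the surfaces can reach inside narrow bounds
  goals <- lapply(fits, function(f) {
    desirability_goal(f$response_name, "target", target = 119,
                      low = 118, high = 120)
  })
  expect_warning(sol <- optimize_desirability(fits, goals), "zero")
  expect_equal(nrow(sol), 0L)
})

test_that("equal-desirability ties rank the lower total concentration first", {
  # one response, flat surface: every point is on target, D = 1 everywhere
  cfg <- noiseless_config()
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  tab <- generate_ccd_response_table(cfg, des, responses = "A549")
  fit <- fit_quadratic(des, tab)
  fit$beta <- c(b0 = 50, b_tm = 0, b_bp = 0, b_tm2 = 0, b_bp2 = 0, b_tmbp = 0)
  goal <- desirability_goal("A549", "target", target = 50, low = 0, high = 100)
  sol <- optimize_desirability(list(fit), list(goal), k = 3)
  expect_equal(sol$desirability[1], 1)
  total <- sol$tm_ug_ml + sol$bp_ug_ml
  expect_true(all(diff(total) >= -1e-9))
  expect_equal(total[1], 10 + 200, tolerance = 1e-6)
})
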