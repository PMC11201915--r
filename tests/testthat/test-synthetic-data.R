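test_that("generator configuration validates its invariants", {
  expect_s3_class(generator_config(seed = 3), "generator_config")
  expect_error(generator_config(noise_cv = -0.1), "noise_cv")
  expect_error(generator_config(replicates = 0), "replicates")
  bad_lines <- data.frame(name = "X", true_m = -1, true_Dm = 50)
  expect_error(generator_config(cell_lines = bad_lines), "true_m")
  expect_error(generator_config(bp_max_effect = 1.5), "fraction")
})

test_that("single-agent generation follows the median-effect curve exactly when noiseless", {
  cfg <- noiseless_config()
  tab <- generate_single_agent_table(cfg, "TM", "A549",
                                     c(0.01, 25, 77.8, 150))
  at_dm <- tab$viability_pct[tab$concentration_ug_ml == 77.8]
  expect_equal(unique(at_dm), 50, tolerance = 1e-12)
  # zero-dose limit: viability -> 100%
  near_zero <- tab$viability_pct[tab$concentration_ug_ml == 0.01]
  expect_true(all(near_zero > 99.99))
  # m = 1 cell line: 50% exactly at Dm regardless of slope
  cfg1 <- generator_config(
    seed = 1, noise_cv = 0,
    cell_lines = data.frame(name = "L", true_m = 1, true_Dm = 77.8)
  )
  tab1 <- generate_single_agent_table(cfg1, "TM", "L", c(38.9, 77.8, 155.6))
  expect_equal(tab1$viability_pct[tab1$concentration_ug_ml == 77.8][1], 50)
})

test_that("generators reject invalid dose and time grids", {
  cfg <- noiseless_config()
  expect_error(generate_single_agent_table(cfg, "TM", "A549", c(-5, 10)),
               "positive")
  expect_error(generate_single_agent_table(cfg, "TM", "A549", c(10, 10)),
               "increasing")
  expect_error(generate_single_agent_table(cfg, "TM", "HeLa", 10), "cell line")
  expect_error(generate_time_course(cfg, "TM", times = numeric(0)),
               "non-empty")
  expect_error(generate_time_course(cfg, "TM", times = c(4, 2)), "increasing")
})

test_that("a fixed seed reproduces bit-identical tables", {
  cfg <- generator_config(seed = 7, noise_cv = 0.08)
  a1 <- generate_single_agent_table(cfg, "TM", "A549", c(25, 50, 100))
  a2 <- generate_single_agent_table(cfg, "TM", "A549", c(25, 50, 100))
  expect_identical(a1, a2)
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  expect_identical(generate_ccd_response_table(cfg, des),
                   generate_ccd_response_table(cfg, des))
  expect_identical(generate_time_course(cfg, "TMBP"),
                   generate_time_course(cfg, "TMBP"))
  # different seeds decorrelate
  cfg2 <- generator_config(seed = 8, noise_cv = 0.08)
  expect_false(identical(
    a1, generate_single_agent_table(cfg2, "TM", "A549", c(25, 50, 100))))
})

test_that("generators leave the session RNG stream untouched", {
  set.seed(99)
  expected <- stats::runif(1)
  set.seed(99)
  invisible(generate_single_agent_table(generator_config(seed = 5),
                                        "TM", "A549", c(25, 50)))
  expect_identical(stats::runif(1), expected)
})

test_that("noiseless CCD responses lie exactly on the ground-truth surface", {
  cfg <- noiseless_config()
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  tab <- generate_ccd_response_table(cfg, des)
  for (cl in names(cfg$surface_coeffs)) {
    rows <- tab[tab$cell_line == cl, ]
    b <- cfg$surface_coeffs[[cl]]
    truth <- b[1] + b[2] * rows$tm_ug_ml + b[3] * rows$bp_ug_ml +
      b[4] * rows$tm_ug_ml^2 + b[5] * rows$bp_ug_ml^2 +
      b[6] * rows$tm_ug_ml * rows$bp_ug_ml
    expect_equal(rows$viability_pct, truth, tolerance = 1e-12)
  }
})

test_that("center-point replicates have nonzero spread under noise", {
  cfg <- generator_config(seed = 21, noise_cv = 0.05)
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  tab <- generate_ccd_response_table(cfg, des, responses = "A549")
  centers <- tab[tab$tm_ug_ml == 30 & tab$bp_ug_ml == 300, ]
  expect_gte(nrow(centers), 2L)
  expect_gt(stats::sd(centers$viability_pct), 0)
})

test_that("noiseless RSM fit on generated responses recovers the surface coefficients", {
  cfg <- noiseless_config()
  des <- build_ccd(paper_levels_tm(), paper_levels_bp())
  tab <- generate_ccd_response_table(cfg, des)
  for (cl in names(cfg$surface_coeffs)) {
    fit <- fit_quadratic(des, tab[tab$cell_line == cl, ])
    expect_equal(unname(fit$beta), unname(cfg$surface_coeffs[[cl]]),
                 tolerance = 1e-8)
  }
})

test_that("time courses are linear with configured slopes and floor at zero", {
  cfg <- noiseless_config()
  # flat series: a blank with zero consumption stays at the initial signal
  cfg_flat <- cfg
  cfg_flat$decay$blank_sigma_cc <- 0
  flat <- generate_time_course(cfg_flat, "bTM")
  expect_true(all(flat$concentration_nmol_ml == cfg$decay$initial_signal))
  # configured activity is recovered by the kinetics chain (round-trip)
  tc <- generate_time_course(cfg, "TM", cell_line = "NCI-H292")
  bl <- generate_time_course(cfg, "bTM")
  act <- cc_activity(consumption_rate(tc, n0 = cfg$decay$n0_nmol),
                     consumption_rate(bl, n0 = cfg$decay$n0_nmol),
                     cc_mass = cfg$decay$cc_mass_ug)
  expect_equal(act, cfg$decay$activities[["NCI-H292"]][["TM"]],
               tolerance = 1e-9)
})

test_that("Dm recovery from noisy tables is nearly unbiased at assay noise", {
  doses <- c(25, 50, 75, 100, 125, 150)
  dms <- vapply(1:200, function(s) {
    cfg <- generator_config(seed = s, noise_cv = 0.05, replicates = 3)
    fit <- fit_median_effect(
      generate_single_agent_table(cfg, "TM", "A549", doses))
    fit$Dm
  }, numeric(1))
  expect_lt(abs(mean(dms) - 77.8) / 77.8, 0.05)
})
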