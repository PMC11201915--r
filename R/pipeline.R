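#' Configure an end-to-end synergy-analysis pipeline run
#'
#' In synthetic mode (the default) every input table is produced by the
#' seeded generator; alternatively, paths to single-agent, combination and
#' time-course CSVs in the package dialects can be supplied.
#'
#' @param seed Integer master seed; recorded in every output header and
#'   used for all generator randomness.
#' @param out_dir Output directory for stage CSVs, plots and the manifest.
#' @param generator A [generator_config()]; its seed is overridden by
#'   `seed`.
#' @param single_agent_csv,combination_csv,time_course_csv Optional input
#'   paths; when all three are `NULL` the pipeline runs in synthetic mode.
#' @param tm_doses,bp_doses Single-agent dose grids (synthetic mode),
#'   ug/mL.
#' @param levels_tm,levels_bp Five-level CCD concentration grids, ug/mL.
#' @param n_center Center-point replicates in the CCD.
#' @param target_viability Desirability target, % viability (50 = EC50).
#' @param ci_tol Additivity tolerance for CI classification.
#' @param plots Write PNG figures?
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("synergy-run-"),
                            generator = generator_config(seed = seed),
                            single_agent_csv = NULL,
                            combination_csv = NULL,
                            time_course_csv = NULL,
                            tm_doses = c(25, 50, 75, 100, 125, 150),
                            bp_doses = c(50, 100, 200, 300, 400),
                            levels_tm = seq(10, 50, by = 10),
                            levels_bp = seq(200, 400, by = 50),
                            n_center = 6L,
                            target_viability = 50,
                            ci_tol = 0.05,
                            plots = FALSE) {
  assert_number(seed, "seed")
  assert_number(target_viability, "target_viability", positive = TRUE)
  generator$seed <- as.integer(seed)
  paths <- list(single_agent = single_agent_csv,
                combination = combination_csv,
                time_course = time_course_csv)
  synthetic <- all(vapply(paths, is.null, logical(1)))
  if (!synthetic) {
    for (nm in names(paths)) {
      if (is.null(paths[[nm]])) {
        stopf("file mode needs all three input CSVs; `%s` is missing", nm)
      }
    }
    for (nm in names(paths)) {
      if (!file.exists(paths[[nm]])) {
        stopf("input file not found (%s): %s", nm, paths[[nm]])
      }
    }
  }
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, generator = generator,
         paths = paths, synthetic = synthetic,
         tm_doses = tm_doses, bp_doses = bp_doses,
         levels_tm = levels_tm, levels_bp = levels_bp,
         n_center = as.integer(n_center),
         target_viability = target_viability,
         ci_tol = ci_tol, plots = isTRUE(plots)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML fields mirror the arguments of [pipeline_config()]; generator
#' fields may be given under a `generator:` block (`noise_cv`,
#' `replicates`, `bp_max_effect`).
#'
#' @param path YAML file path.
#' @param ... Overrides passed on to [pipeline_config()].
#' @return Object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  gen_args <- y$generator %||% list()
  y$generator <- NULL
  args <- utils::modifyList(y, list(...))
  if (!is.null(args$seed)) gen_args$seed <- args$seed
  args$generator <- do.call(generator_config, gen_args)
  do.call(pipeline_config, args)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full synergy-analysis pipeline
#'
#' Executes, in order: data generation (or loading), single-agent
#' median-effect fits, CCD construction and quadratic response-surface
#' fits for both cancer lines, desirability optimization toward the target
#' viability, combination-index scoring of the measured combinations plus
#' the selected optimum, and consumption kinetics. Every stage writes a
#' CSV (with seed and config fingerprint in a `#` header line) to
#' `config$out_dir`, and a `manifest.json` records the seed, package
#' version, fingerprint and per-file MD5 checksums. With a fixed seed the
#' synthetic-mode outputs are byte-identical across reruns.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted objects and result tables:
#'   `dose_response_fits`, `design`, `rsm_fits`, `solutions`, `ci`,
#'   `kinetics`, `manifest`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 42, out_dir = tempfile())
#' res <- run_pipeline(cfg)
#' res$solutions
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # fingerprint the scientific configuration only, not the output location
  fp <- object_fingerprint(unclass(config)[setdiff(names(config),
                                                   c("out_dir", "plots"))])
  gen <- config$generator
  cancer_lines <- intersect(gen$cell_lines$name, names(gen$surface_coeffs))
  emit <- function(df, name) {
    write_stage_csv(df, file.path(config$out_dir, name), config$seed, fp)
  }

  # --- stage: inputs -------------------------------------------------------
  inputs <- with_stage("inputs", {
    if (config$synthetic) {
      sa <- rbind(
        do.call(rbind, lapply(gen$cell_lines$name, function(cl) {
          generate_single_agent_table(gen, "TM", cl, config$tm_doses)
        })),
        do.call(rbind, lapply(gen$cell_lines$name, function(cl) {
          generate_single_agent_table(gen, "BP", cl, config$bp_doses)
        }))
      )
      design <- build_ccd(config$levels_tm, config$levels_bp, config$n_center)
      combo <- generate_ccd_response_table(gen, design, cancer_lines,
                                           replicates = gen$replicates)
      tc <- rbind(
        generate_time_course(gen, "bTM"),
        do.call(rbind, lapply(cancer_lines, function(cl) {
          rbind(generate_time_course(gen, "TM", cell_line = cl),
                generate_time_course(gen, "TMBP", cell_line = cl))
        }))
      )
      list(single_agent = sa, design = design, combination = combo,
           time_course = tc)
    } else {
      design <- build_ccd(config$levels_tm, config$levels_bp, config$n_center)
      list(
        single_agent = read_dose_response_csv(config$paths$single_agent),
        design = design,
        combination = read_stage_csv(config$paths$combination),
        time_course = read_time_course_csv(config$paths$time_course)
      )
    }
  })
  emit(inputs$single_agent, "single_agent_viability.csv")
  emit(inputs$combination, "combination_viability.csv")
  emit(inputs$time_course, "time_course.csv")
  emit(inputs$design$runs, "ccd_design.csv")

  # --- stage: dose-response fits ------------------------------------------
  dr_fits <- with_stage("dose_response", {
    sa <- inputs$single_agent
    fits <- list()
    for (ag in unique(sa$agent)) {
      for (cl in unique(sa$cell_line[sa$agent == ag])) {
        tab <- sa[sa$agent == ag & sa$cell_line == cl, , drop = FALSE]
        fits[[paste(ag, cl, sep = ".")]] <- fit_median_effect(tab)
      }
    }
    fits
  })
  emit(median_effect_summary(dr_fits), "median_effect_fits.csv")

  # --- stage: response surfaces -------------------------------------------
  rsm_fits <- with_stage("rsm", {
    lapply(stats::setNames(cancer_lines, cancer_lines), function(cl) {
      rows <- inputs$combination[inputs$combination$cell_line == cl, ,
                                 drop = FALSE]
      fit_quadratic(inputs$design, rows, response_name = cl)
    })
  })
  emit(do.call(rbind, lapply(rsm_fits, function(f) {
    data.frame(response = f$response_name, t(f$beta), r2 = f$r2,
               adj_r2 = f$adj_r2, adeq_precision = f$adeq_precision,
               cv_pct = f$cv_pct, lof_f = f$lof_f, lof_p = f$lof_p)
  })), "rsm_fits.csv")

  # --- stage: desirability -------------------------------------------------
  solutions <- with_stage("desirability", {
    goals <- lapply(rsm_fits, function(f) {
      b <- predicted_response_bounds(f)
      desirability_goal(f$response_name, "target",
                        target = config$target_viability,
                        low = b[["low"]], high = b[["high"]])
    })
    optimize_desirability(unname(rsm_fits), unname(goals), k = 5L)
  })
  emit(as.data.frame(solutions), "desirability_solutions.csv")
  if (nrow(solutions) == 0L) {
    stopf("stage 'desirability' failed: no acceptable combination in the region")
  }
  optimum <- solutions[1L, ]

  # --- stage: combination index -------------------------------------------
  ci_tables <- with_stage("synergy_ci", {
    lapply(stats::setNames(cancer_lines, cancer_lines), function(cl) {
      tm_fit <- dr_fits[[paste("TM", cl, sep = ".")]]
      bp_fit <- dr_fits[[paste("BP", cl, sep = ".")]]
      combo <- inputs$combination[inputs$combination$cell_line == cl, ,
                                  drop = FALSE]
      meas <- stats::aggregate(viability_pct ~ tm_ug_ml + bp_ug_ml,
                               data = combo, FUN = mean)
      opt_row <- data.frame(
        tm_ug_ml = optimum$tm_ug_ml, bp_ug_ml = optimum$bp_ug_ml,
        viability_pct = optimum[[paste0("pred_", cl)]]
      )
      curve <- ci_fa_curve(rbind(meas, opt_row), tm_fit, bp_fit,
                           tol = config$ci_tol)
      curve$cell_line <- cl
      curve
    })
  })
  ci_all <- do.call(rbind, ci_tables)
  rownames(ci_all) <- NULL
  emit(ci_all, "combination_index.csv")

  # --- stage: kinetics -----------------------------------------------------
  kin <- with_stage("kinetics", {
    tc <- inputs$time_course
    dk <- gen$decay
    blank <- consumption_rate(tc[tc$condition == "bTM", , drop = FALSE],
                              n0 = dk$n0_nmol)
    rows <- lapply(cancer_lines, function(cl) {
      do.call(rbind, lapply(c("TM", "TMBP"), function(cond) {
        sub <- tc[tc$condition == cond & tc$cell_line == cl, , drop = FALSE]
        if (nrow(sub) == 0L) return(NULL)
        f <- consumption_rate(sub, n0 = dk$n0_nmol)
        data.frame(condition = cond, cell_line = cl,
                   sigma_cc_nmol_h = f$sigma_cc,
                   cc_activity_nmol_h_ug = cc_activity(f, blank, dk$cc_mass_ug),
                   r2 = f$r2)
      }))
    })
    list(blank = blank, table = do.call(rbind, rows))
  })
  kin_tab <- rbind(
    data.frame(condition = "bTM", cell_line = "none",
               sigma_cc_nmol_h = kin$blank$sigma_cc,
               cc_activity_nmol_h_ug = NA_real_, r2 = kin$blank$r2),
    kin$table
  )
  emit(kin_tab, "consumption_kinetics.csv")

  if (config$plots) {
    with_stage("plots", pipeline_plots(config, inputs, rsm_fits, solutions,
                                       ci_tables))
  }

  # --- manifest ------------------------------------------------------------
  files <- sort(list.files(config$out_dir, pattern = "\\.csv$"))
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("synergyrsm")),
    config_fingerprint = unname(fp),
    files = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(config$out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    dose_response_fits = dr_fits,
    design = inputs$design,
    rsm_fits = rsm_fits,
    solutions = solutions,
    ci = ci_all,
    kinetics = kin_tab,
    manifest = manifest
  ))
}

# PNG figures: dose-response curves, 3-D viability surfaces, desirability
# contour, CI-Fa plot, kinetic time courses.
pipeline_plots <- function(config, inputs, rsm_fits, solutions, ci_tables) {
  png_to <- function(name, expr, width = 900, height = 700) {
    grDevices::png(file.path(config$out_dir, name), width = width,
                   height = height, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
  }
  sa <- inputs$single_agent
  png_to("dose_response.png", {
    tm <- sa[sa$agent == "TM", ]
    graphics::plot(NULL, xlim = range(tm$concentration_ug_ml),
                   ylim = c(0, 110), xlab = "TM concentration (ug/mL)",
                   ylab = "viability (%)", main = "Single-agent dose-response")
    lines <- unique(tm$cell_line)
    for (i in seq_along(lines)) {
      sub <- stats::aggregate(viability_pct ~ concentration_ug_ml,
                              data = tm[tm$cell_line == lines[i], ], FUN = mean)
      graphics::lines(sub$concentration_ug_ml, sub$viability_pct, col = i,
                      type = "b", pch = 19)
    }
    graphics::legend("bottomleft", legend = lines, col = seq_along(lines),
                     lty = 1, pch = 19, bty = "n")
  })
  for (nm in names(rsm_fits)) {
    f <- rsm_fits[[nm]]
    png_to(paste0("surface_", gsub("[^A-Za-z0-9]", "_", nm), ".png"), {
      tm <- seq(f$region$tm[1], f$region$tm[2], length.out = 40)
      bp <- seq(f$region$bp[1], f$region$bp[2], length.out = 40)
      z <- outer(tm, bp, function(a, b) eval_quadratic(unname(f$beta), a, b))
      graphics::persp(tm, bp, z, theta = 35, phi = 25,
                      xlab = "TM (ug/mL)", ylab = "BP (ug/mL)",
                      zlab = "viability (%)", ticktype = "detailed",
                      main = paste("Fitted viability surface:", nm))
    })
  }
  png_to("ci_fa.png", {
    ci_all <- do.call(rbind, ci_tables)
    graphics::plot(ci_all$fa, ci_all$ci, xlab = "fraction affected (Fa)",
                   ylab = "combination index (CI)", pch = 19,
                   col = as.integer(factor(ci_all$cell_line)),
                   ylim = c(0, max(1.2, max(ci_all$ci) * 1.1)),
                   main = "CI-Fa")
    graphics::abline(h = 1, lty = 2)
  })
  png_to("time_course.png", {
    tc <- inputs$time_course
    key <- paste(tc$condition, tc$cell_line)
    graphics::plot(NULL, xlim = range(tc$time_h),
                   ylim = c(0, max(tc$concentration_nmol_ml) * 1.05),
                   xlab = "time (h)", ylab = "signal",
                   main = "Compound decay time courses")
    ks <- unique(key)
    for (i in seq_along(ks)) {
      sub <- stats::aggregate(concentration_nmol_ml ~ time_h,
                              data = tc[key == ks[i], ], FUN = mean)
      graphics::lines(sub$time_h, sub$concentration_nmol_ml, col = i,
                      type = "b", pch = 19)
    }
    graphics::legend("bottomleft", legend = ks, col = seq_along(ks),
                     lty = 1, pch = 19, bty = "n", cex = 0.8)
  })
  invisible(NULL)
}
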