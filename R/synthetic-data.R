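#' Configuration for the synthetic assay-data generator
#'
#' Builds the ground-truth description of a two-extract cytotoxicity study:
#' median-effect dose-response curves per cell line for the toxic extract
#' (TM, turmeric), a near-flat response for the essentially non-toxic
#' partner (BP, black pepper), quadratic ground-truth combination surfaces
#' over the design region, and linear-in-time compound decay for the
#' consumption-kinetics time courses. All generators draw replicate noise
#' from seeded substreams of `seed`, so a fixed configuration reproduces
#' bit-identical tables.
#'
#' The defaults encode the study conditions this package models: TM EC50s of
#' 77.8 ug/mL (A549) and 92.0 ug/mL (NCI-H292), a resistant normal
#' fibroblast line (MRC-5), BP causing at most ~8% cell death at its top
#' tested concentration of 400 ug/mL, combination surfaces whose 50%
#' viability contours intersect at an interior point of the design region
#' (TM 48.5, BP 241.7 ug/mL), and decay slopes derived from target
#' consumption activities so the kinetics stage recovers them exactly in
#' the noiseless limit.
#'
#' @param seed Integer master RNG seed.
#' @param cell_lines Data frame with columns `name`, `true_m` (unitless
#'   median-effect slope, > 0) and `true_Dm` (ug/mL, > 0) describing the TM
#'   dose-response per cell line.
#' @param bp_max_effect Fraction affected caused by BP at `bp_ref_dose`
#'   (small; the BP curve ramps linearly from 0 to this value).
#' @param bp_ref_dose Top tested BP concentration, ug/mL.
#' @param surface_coeffs Named list of length-6 coefficient vectors
#'   `(b0, b_tm, b_bp, b_tm2, b_bp2, b_tmbp)` in natural units (% viability
#'   per ug/mL powers), one per response (cell line).
#' @param noise_cv Coefficient of variation of multiplicative replicate
#'   noise (fraction, >= 0).
#' @param replicates Integer number of replicates (>= 1).
#' @param decay List describing the time-course generator:
#'   `initial_signal` (signal units at t = 0), `n0_nmol` (initial compound
#'   moles), `cc_mass_ug` (initial compound mass used for normalization),
#'   `blank_sigma_cc` (abiotic consumption rate, nmol/h) and `activities`,
#'   a named list per cell line of target consumption activities
#'   (nmol/h/ug) for the cell-containing conditions `TM` and `TMBP`.
#' @return An object of class `generator_config`.
#' @seealso [generate_single_agent_table()], [generate_ccd_response_table()],
#'   [generate_time_course()]
#' @export
#' @examples
#' cfg <- generator_config(seed = 1)
#' cfg
generator_config <- function(seed = 1L,
                             cell_lines = default_cell_lines(),
                             bp_max_effect = 0.08,
                             bp_ref_dose = 400,
                             surface_coeffs = default_surface_coeffs(),
                             noise_cv = 0.05,
                             replicates = 3L,
                             decay = default_decay()) {
  assert_number(seed, "seed")
  assert_number(bp_max_effect, "bp_max_effect")
  assert_number(bp_ref_dose, "bp_ref_dose", positive = TRUE)
  assert_number(noise_cv, "noise_cv")
  assert_number(replicates, "replicates")
  if (noise_cv < 0) stopf("`noise_cv` must be >= 0")
  if (replicates < 1) stopf("`replicates` must be >= 1")
  if (bp_max_effect < 0 || bp_max_effect > 1) {
    stopf("`bp_max_effect` must be a fraction in [0, 1]")
  }
  assert_columns(cell_lines, c("name", "true_m", "true_Dm"), "cell_lines")
  if (any(cell_lines$true_m <= 0) || any(cell_lines$true_Dm <= 0)) {
    stopf("`true_m` and `true_Dm` must be > 0 for every cell line")
  }
  for (nm in names(surface_coeffs)) {
    if (length(surface_coeffs[[nm]]) != 6L || !is.numeric(surface_coeffs[[nm]])) {
      stopf("surface_coeffs[['%s']] must be 6 numeric coefficients", nm)
    }
  }
  for (fld in c("initial_signal", "n0_nmol", "cc_mass_ug", "blank_sigma_cc")) {
    assert_number(decay[[fld]], paste0("decay$", fld))
  }
  if (decay$initial_signal <= 0 || decay$n0_nmol <= 0 || decay$cc_mass_ug <= 0) {
    stopf("decay initial signal, n0 and cc mass must be > 0")
  }
  structure(
    list(
      seed = as.integer(seed),
      cell_lines = cell_lines,
      bp_max_effect = bp_max_effect,
      bp_ref_dose = bp_ref_dose,
      surface_coeffs = surface_coeffs,
      noise_cv = noise_cv,
      replicates = as.integer(replicates),
      decay = decay
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic assay generator configuration\n")
  cat("  seed:        ", x$seed, "\n", sep = "")
  cat("  cell lines:  ",
      paste(sprintf("%s (m=%.3g, Dm=%.4g)", x$cell_lines$name,
                    x$cell_lines$true_m, x$cell_lines$true_Dm),
            collapse = "; "), "\n", sep = "")
  cat("  BP max effect: ", x$bp_max_effect, " at ", x$bp_ref_dose, " ug/mL\n",
      sep = "")
  cat("  surfaces:    ", paste(names(x$surface_coeffs), collapse = ", "),
      "\n", sep = "")
  cat("  noise CV:    ", x$noise_cv, "   replicates: ", x$replicates, "\n",
      sep = "")
  invisible(x)
}

#' Default ground-truth cell-line parameters
#'
#' TM median-effect parameters: EC50 77.8 ug/mL (A549) and 92.0 ug/mL
#' (NCI-H292); MRC-5 is resistant (cytotoxicity only appears at the top
#' tested concentration).
#' @return Data frame with columns `name`, `true_m`, `true_Dm`.
#' @export
default_cell_lines <- function() {
  data.frame(
    name = c("A549", "NCI-H292", "MRC-5"),
    true_m = c(2.0, 2.2, 4.0),
    true_Dm = c(77.8, 92.0, 220),
    stringsAsFactors = FALSE
  )
}

#' Default ground-truth combination surfaces
#'
#' Quadratic viability surfaces (% viability) over TM 10-50, BP 200-400
#' ug/mL for the two cancer lines. The slope/curvature terms make A549
#' predominantly TM-driven and NCI-H292 relatively more BP-sensitive, and
#' each intercept is anchored so both surfaces pass through exactly 50%
#' viability at TM = 48.5, BP = 241.7 ug/mL — the interior point where the
#' two 50% contours cross, which the desirability stage should find with
#' overall desirability 1.
#' @return Named list of length-6 coefficient vectors
#'   `(b0, b_tm, b_bp, b_tm2, b_bp2, b_tmbp)`.
#' @export
default_surface_coeffs <- function() {
  anchor <- c(tm = 48.5, bp = 241.7)
  mk <- function(slopes) {
    b0 <- 50 - sum(slopes * quad_basis(anchor[["tm"]], anchor[["bp"]])[-1])
    c(b0 = unname(b0), slopes)
  }
  list(
    "A549" = mk(c(b_tm = -0.9, b_bp = -0.02, b_tm2 = -0.002,
                  b_bp2 = -1e-5, b_tmbp = -4e-4)),
    "NCI-H292" = mk(c(b_tm = -0.15, b_bp = -0.16, b_tm2 = -0.001,
                      b_bp2 = -6e-5, b_tmbp = -3e-4))
  )
}

#' Default time-course decay configuration
#'
#' Signal decays linearly from 100 units. Per-condition slopes are derived
#' from target consumption activities (nmol/h/ug): the blank (bTM, medium
#' without cells) decays at the abiotic rate, and the cell-containing
#' conditions (TM alone; TMBP, the TM + BP combination) at the rate implied
#' by `activity * cc_mass + blank`. `cc_mass_ug` defaults to the curcumin
#' mass per mL of medium dosed at 48.5 ug/mL extract with 26.7 ug curcumin
#' per mg extract.
#' @return List with fields `initial_signal`, `n0_nmol`, `cc_mass_ug`,
#'   `blank_sigma_cc` and `activities`.
#' @export
default_decay <- function() {
  list(
    initial_signal = 100,
    n0_nmol = 2000,
    cc_mass_ug = curcumin_mass(48.5),
    blank_sigma_cc = 10,
    activities = list(
      "A549" = c(TM = 116.14, TMBP = 49.72),
      "NCI-H292" = c(TM = 76.02, TMBP = 47.53)
    )
  )
}

# Median-effect fraction affected at dose D for slope m and median-effect
# dose Dm: fa = (D/Dm)^m / (1 + (D/Dm)^m).
median_effect_fa <- function(dose, m, Dm) {
  r <- (dose / Dm)^m
  r / (1 + r)
}

# Multiplicative replicate noise, truncated to the plate-reader range.
apply_replicate_noise <- function(mean_value, noise_cv, lo = 0, hi = 120) {
  eps <- stats::rnorm(length(mean_value), mean = 0, sd = noise_cv)
  pmin(pmax(mean_value * (1 + eps), lo), hi)
}

#' Generate a replicated single-agent dose-response table
#'
#' Mean viability follows the median-effect model for agent `"TM"`
#' (`viability = 100 * (1 - fa)` with `fa = (D/Dm)^m / (1 + (D/Dm)^m)`), or
#' a shallow linear effect ramp for the near-non-toxic agent `"BP"`
#' (`fa = bp_max_effect * D / bp_ref_dose`). Replicates are the mean times
#' `(1 + eps)` with `eps ~ N(0, noise_cv)`, truncated to [0, 120]%.
#'
#' @param config A [generator_config()].
#' @param agent `"TM"` or `"BP"`.
#' @param cell_line Cell-line name; for TM it must appear in
#'   `config$cell_lines`.
#' @param doses Strictly increasing positive concentrations, ug/mL.
#' @return Data frame with columns `agent`, `cell_line`,
#'   `concentration_ug_ml`, `replicate`, `viability_pct`.
#' @export
#' @examples
#' cfg <- generator_config(seed = 7, noise_cv = 0)
#' tab <- generate_single_agent_table(cfg, "TM", "A549", c(25, 50, 77.8, 150))
#' subset(tab, concentration_ug_ml == 77.8)  # exactly 50% viability at Dm
generate_single_agent_table <- function(config, agent, cell_line, doses) {
  stopifnot(inherits(config, "generator_config"))
  agent <- match.arg(agent, c("TM", "BP"))
  if (!is.numeric(doses) || length(doses) < 1L) stopf("`doses` must be numeric")
  if (any(doses <= 0)) stopf("doses must be strictly positive")
  if (any(diff(doses) <= 0)) stopf("doses must be strictly increasing")

  if (agent == "TM") {
    row <- config$cell_lines[config$cell_lines$name == cell_line, , drop = FALSE]
    if (nrow(row) != 1L) stopf("unknown cell line '%s'", cell_line)
    fa <- median_effect_fa(doses, row$true_m, row$true_Dm)
  } else {
    fa <- config$bp_max_effect * doses / config$bp_ref_dose
  }
  mean_viab <- 100 * (1 - fa)

  out <- with_seed(
    stage_seed(config$seed, 11L, paste(agent, cell_line)),
    {
      reps <- lapply(seq_len(config$replicates), function(r) {
        data.frame(
          agent = agent,
          cell_line = cell_line,
          concentration_ug_ml = doses,
          replicate = r,
          viability_pct = apply_replicate_noise(mean_viab, config$noise_cv),
          stringsAsFactors = FALSE
        )
      })
      do.call(rbind, reps)
    }
  )
  out[order(out$concentration_ug_ml, out$replicate), , drop = FALSE]
}

# Evaluate the quadratic surface basis (1, tm, bp, tm^2, bp^2, tm*bp).
quad_basis <- function(tm, bp) {
  cbind(1, tm, bp, tm^2, bp^2, tm * bp)[1, ]
}

# Vectorized quadratic surface evaluation.
eval_quadratic <- function(coeffs, tm, bp) {
  coeffs[1] + coeffs[2] * tm + coeffs[3] * bp +
    coeffs[4] * tm^2 + coeffs[5] * bp^2 + coeffs[6] * tm * bp
}

#' Generate combination responses on a central composite design
#'
#' Evaluates the ground-truth quadratic viability surface of each requested
#' response at every design run and adds multiplicative replicate noise,
#' clipped to [0, 120]%. Center-point replication in the design provides
#' the pure-error degrees of freedom downstream.
#'
#' @param config A [generator_config()].
#' @param design A [build_ccd()] design.
#' @param responses Character vector of response (cell-line) names; default
#'   all surfaces in the configuration.
#' @param replicates Replicate measurements per design run (default 1: the
#'   design's own center replication carries the pure error; set to
#'   `config$replicates` to emulate repeated whole-design experiments).
#' @return Data frame with columns `run`, `tm_ug_ml`, `bp_ug_ml`,
#'   `cell_line`, `replicate`, `viability_pct`.
#' @export
generate_ccd_response_table <- function(config, design,
                                        responses = names(config$surface_coeffs),
                                        replicates = 1L) {
  stopifnot(inherits(config, "generator_config"))
  stopifnot(inherits(design, "ccd_design"))
  missing <- setdiff(responses, names(config$surface_coeffs))
  if (length(missing)) {
    stopf("no ground-truth surface for response(s): %s",
          paste(missing, collapse = ", "))
  }
  if (replicates < 1L) stopf("`replicates` must be >= 1")
  pts <- design$runs
  out <- lapply(responses, function(nm) {
    mean_viab <- eval_quadratic(config$surface_coeffs[[nm]],
                                pts$tm_ug_ml, pts$bp_ug_ml)
    with_seed(stage_seed(config$seed, 23L, nm), {
      do.call(rbind, lapply(seq_len(replicates), function(r) {
        data.frame(
          run = pts$run,
          tm_ug_ml = pts$tm_ug_ml,
          bp_ug_ml = pts$bp_ug_ml,
          cell_line = nm,
          replicate = r,
          viability_pct = apply_replicate_noise(mean_viab, config$noise_cv),
          stringsAsFactors = FALSE
        )
      }))
    })
  })
  do.call(rbind, out)
}

#' Generate a compound-decay time course
#'
#' Signal decays linearly: `signal(t) = initial - slope * t`, floored at 0,
#' with multiplicative replicate noise. The per-condition slope is derived
#' from the configured consumption rates so that the kinetics estimator
#' recovers the configured activity exactly on noiseless output:
#' `slope = sigma_cc * initial_signal / n0_nmol`, where `sigma_cc` is the
#' blank rate for `bTM` and `activity * cc_mass + blank` for the
#' cell-containing conditions.
#'
#' @param config A [generator_config()].
#' @param condition `"bTM"` (medium without cells), `"TM"` or `"TMBP"`.
#' @param times Non-negative, strictly increasing sampling times, h.
#' @param cell_line Cell line for the cell-containing conditions (ignored
#'   for `"bTM"`).
#' @return Data frame with columns `condition`, `cell_line`, `time_h`,
#'   `concentration_nmol_ml`, `replicate`.
#' @export
generate_time_course <- function(config, condition, times = c(2, 4, 6, 8, 10),
                                 cell_line = "A549") {
  stopifnot(inherits(config, "generator_config"))
  condition <- match.arg(condition, c("bTM", "TM", "TMBP"))
  if (length(times) == 0L) stopf("`times` must be non-empty")
  if (any(times < 0)) stopf("times must be non-negative")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")

  dk <- config$decay
  sigma_cc <- if (condition == "bTM") {
    dk$blank_sigma_cc
  } else {
    act <- dk$activities[[cell_line]]
    if (is.null(act) || is.na(act[condition])) {
      stopf("no configured activity for condition '%s' on cell line '%s'",
            condition, cell_line)
    }
    act[[condition]] * dk$cc_mass_ug + dk$blank_sigma_cc
  }
  slope <- sigma_cc * dk$initial_signal / dk$n0_nmol
  mean_signal <- pmax(dk$initial_signal - slope * times, 0)

  line_tag <- if (condition == "bTM") "none" else cell_line
  with_seed(
    stage_seed(config$seed, 37L, paste(condition, line_tag)),
    {
      reps <- lapply(seq_len(config$replicates), function(r) {
        data.frame(
          condition = condition,
          cell_line = line_tag,
          time_h = times,
          concentration_nmol_ml = pmax(
            mean_signal * (1 + stats::rnorm(length(times), 0, config$noise_cv)),
            0
          ),
          replicate = r,
          stringsAsFactors = FALSE
        )
      })
      do.call(rbind, reps)
    }
  )
}
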