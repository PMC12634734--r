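# One-at-a-time sensitivity analysis: parameter sweeps (one full solve per
# factor, everything else at baseline), the normalized sensitivity
# s = (relative output change) / (input factor change) as a least-squares
# slope over the sweep, perturbation studies (attachment shift, contact law
# type, friction, overclosure) and the mesh-convergence study.

#' Inputs recognized by the sweep driver
#' @return Character vector of input names.
#' @export
sensitivity_inputs <- function() {
  c("ligament_reference_length", "ligament_stiffness", "load_intensity",
    "friction", "overclosure", "attachment_shift")
}

# rebuild/adjust the model and load for one input factor
.apply_factor <- function(builder_args, input, factor) {
  ba <- builder_args
  switch(input,
    ligament_reference_length = { ba$ref_scale <- factor },
    ligament_stiffness = { ba$stiffness_scale <- ba$stiffness_scale * factor },
    load_intensity = { ba$load_scale <- ba$load_scale * factor },
    friction = { ba$mu <- factor },
    overclosure = { ba$c0_scale <- ba$c0_scale * factor },
    attachment_shift = { ba$attachment_shift_x <- factor },
    stop2("unknown sweep input '%s' (one of: %s)", input,
          paste(sensitivity_inputs(), collapse = ", "))
  )
  ba
}

# solve one configuration and extract the three scalar outputs
.sweep_outputs <- function(model, scenario, load_scale) {
  ld <- scenario; ld$scale <- ld$scale * load_scale
  state <- solve_quasistatic(model, ld)
  sl <- surface_stress_summary(state, "sij_ilium_left")
  sr <- surface_stress_summary(state, "sij_ilium_right")
  km <- joint_kinematics(state)
  c(mean_stress = (sl$mean + sr$mean) / 2,
    mean_translation = mean(km$translation),
    mean_rotation = mean(km$rotation))
}

#' Sweep one model input over a set of factors
#'
#' One full quasi-static solve per factor with all other inputs held at
#' baseline; outputs are the mean ilium-surface von Mises stress and the
#' mean relative joint translation/rotation.
#'
#' @param input One of [sensitivity_inputs()].
#' @param factors Numeric factors (dimensionless multipliers; for
#'   `friction` the friction coefficient itself, for `attachment_shift`
#'   the shift in mm).
#' @param scenario A [load_case()] (default symmetric xyz).
#' @param baseline_factor The factor regarded as baseline (nearest row is
#'   tagged in the result).
#' @param ... Arguments forwarded to [build_sij_model()] (params,
#'   refinement, seed, ...).
#' @return Data frame of class `sij_sweep`: `input, factor, mean_stress,
#'   mean_translation, mean_rotation, baseline`.
#' @export
sweep_parameter <- function(input, factors,
                            scenario = generic_scenarios()$symmetric_xyz,
                            baseline_factor = 1, ...) {
  base_args <- list(...)
  base_args$stiffness_scale <- base_args$stiffness_scale %||% 1
  base_args$c0_scale <- base_args$c0_scale %||% 1
  base_args$load_scale <- 1
  rows <- list()
  for (f in factors) {
    ba <- .apply_factor(base_args, input, f)
    load_scale <- ba$load_scale; ba$load_scale <- NULL
    ref_scale <- ba$ref_scale %||% 1; ba$ref_scale <- NULL
    model <- do.call(build_sij_model, ba)
    model$ref_scale <- ref_scale
    out <- tryCatch(.sweep_outputs(model, scenario, load_scale),
                    sij_no_convergence = function(e)
                      stop2("sweep aborted: no convergence at %s factor %.4g", input, f))
    rows[[length(rows) + 1L]] <- data.frame(input = input, factor = f,
                                            t(out), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$baseline <- seq_len(nrow(res)) == which.min(abs(res$factor - baseline_factor))
  class(res) <- c("sij_sweep", class(res))
  res
}

#' Normalized sensitivity from a sweep table
#'
#' `s = (relative change in output w.r.t. the baseline output) / (change in
#' input factor)`, computed as the least-squares slope of
#' `(output/output_baseline - 1)` against the factor over all sweep points.
#' Negative values mean the output decreases with larger input.
#'
#' @param sweep A data frame from [sweep_parameter()] (or any frame with
#'   `factor`, output columns and a logical `baseline` column).
#' @param output Output column name (default all three standard outputs).
#' @return Data frame: `input, output, sensitivity`.
#' @export
sensitivity <- function(sweep, output = c("mean_stress", "mean_translation",
                                          "mean_rotation")) {
  if (nrow(sweep) < 2L) stop2("sensitivity needs at least 2 sweep points")
  output <- intersect(output, names(sweep))
  ib <- which(sweep$baseline)[1]
  if (is.na(ib)) ib <- which.min(abs(sweep$factor - 1))
  out <- lapply(output, function(oc) {
    y0 <- sweep[[oc]][ib]
    if (!is.finite(y0) || y0 == 0) stop2("zero baseline output for '%s'", oc)
    x <- sweep$factor - sweep$factor[ib]
    y <- sweep[[oc]] / y0 - 1
    s <- sum(x * y) / sum(x * x)  # least-squares slope through the baseline
    data.frame(input = sweep$input[1], output = oc, sensitivity = s,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' The standard sensitivity study
#'
#' Sweeps ligament reference length (0.998 to 1), ligament stiffness (0.6 to
#' 1.4) and load intensity (0.6 to 1.4), three points each, and reports the
#' normalized sensitivities of mean stress, translation and rotation.
#'
#' @param scenario A [load_case()].
#' @param points Sweep points per input (endpoints plus baseline).
#' @param ... Forwarded to [build_sij_model()].
#' @return List with `sweeps` (per-input sweep tables) and `table`
#'   (input x output sensitivity frame).
#' @export
sensitivity_study <- function(scenario = generic_scenarios()$symmetric_xyz,
                              points = 3, ...) {
  ranges <- list(ligament_reference_length = c(0.998, 1),
                 ligament_stiffness = c(0.6, 1.4),
                 load_intensity = c(0.6, 1.4))
  sweeps <- list(); tabs <- list()
  for (input in names(ranges)) {
    r <- ranges[[input]]
    factors <- sort(unique(c(seq(r[1], r[2], length.out = points),
                             min(1, r[2]))))
    sw <- sweep_parameter(input, factors, scenario = scenario, ...)
    sweeps[[input]] <- sw
    tabs[[input]] <- sensitivity(sw)
  }
  list(sweeps = sweeps, table = do.call(rbind, unname(tabs)))
}

#' Perturbation study
#'
#' Percent change of the three outputs relative to baseline for discrete
#' modelling choices: gluteal attachment shifts (10 mm medial / 20 mm
#' lateral), linear vs exponential SIJ contact, friction 0.2--0.6, and
#' overclosure (cartilage thickness surrogate) scaling.
#'
#' @param which Study name.
#' @param scenario A [load_case()].
#' @param ... Forwarded to [build_sij_model()].
#' @return Data frame: `case`, the three outputs, and `pct_change_*` columns
#'   relative to the baseline row.
#' @export
perturbation_study <- function(which = c("attachment_shift", "contact_type",
                                         "friction", "overclosure"),
                               scenario = generic_scenarios()$symmetric_xyz,
                               ...) {
  which <- match.arg(which)
  cases <- switch(which,
    attachment_shift = list(baseline = list(),
                            medial_10mm = list(attachment_shift_x = -10),
                            lateral_20mm = list(attachment_shift_x = 20)),
    contact_type = list(baseline = list(contact_type = "exponential"),
                        linear = list(contact_type = "linear")),
    friction = list(mu_0.2 = list(mu = 0.2), baseline = list(mu = 0.4),
                    mu_0.6 = list(mu = 0.6)),
    overclosure = list(scale_0.75 = list(c0_scale = 0.75),
                       baseline = list(c0_scale = 1),
                       scale_1.25 = list(c0_scale = 1.25))
  )
  base_args <- list(...)
  rows <- list()
  for (cn in names(cases)) {
    ba <- utils::modifyList(base_args, cases[[cn]])
    model <- do.call(build_sij_model, ba)
    out <- .sweep_outputs(model, scenario, 1)
    rows[[cn]] <- data.frame(case = cn, t(out), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  base <- res[res$case == "baseline", ]
  for (oc in c("mean_stress", "mean_translation", "mean_rotation")) {
    res[[paste0("pct_change_", oc)]] <- 100 * (res[[oc]] / base[[oc]] - 1)
  }
  rownames(res) <- NULL
  res
}

#' Mesh convergence study
#'
#' Solves the same scenario on the coarse/medium/fine refinements of one
#' morphology and reports each level's outputs as relative differences
#' against the finest level. Default scenario: symmetric xyz (the scenario
#' with the largest average stresses and joint movements).
#'
#' @param params A [morphology_params()].
#' @param levels Refinement levels, coarsest to finest.
#' @param scenario A [load_case()].
#' @param ... Forwarded to [build_sij_model()].
#' @return Data frame: level, element count, outputs, `rel_diff_*` vs the
#'   finest level, and solve-time ratios vs the coarsest.
#' @export
convergence_study <- function(params = morphology_params(),
                              levels = c("coarse", "medium", "fine"),
                              scenario = generic_scenarios()$symmetric_xyz,
                              ...) {
  rows <- list()
  for (i in seq_along(levels)) {
    t0 <- proc.time()[["elapsed"]]
    model <- build_sij_model(params = params, refinement = levels[i], ...)
    out <- .sweep_outputs(model, scenario, 1)
    dt <- proc.time()[["elapsed"]] - t0
    rows[[i]] <- data.frame(level = levels[i], n_elements = nrow(model$mesh$elems),
                            t(out), seconds = dt, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  fin <- res[nrow(res), ]
  for (oc in c("mean_stress", "mean_translation", "mean_rotation")) {
    res[[paste0("rel_diff_", oc)]] <- abs(res[[oc]] / fin[[oc]] - 1)
  }
  res$time_ratio <- res$seconds / res$seconds[1]
  rownames(res) <- NULL
  res
}
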