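# End-to-end simulation pipeline and validation against the reference set.

#' Simulate unilateral chewing for one or more foods
#'
#' Runs the full pipeline per food: food curve, chewing path, inverse
#' kinematics, quasi-static force solve, temporalis decomposition and
#' metrics. This is the programmatic equivalent of the command-line
#' `simulate` subcommand.
#'
#' @param food_ids Foods to chew; default all five.
#' @param working_side `"right"` or `"left"`.
#' @param v_t Closing speed of the incisal point, m/s.
#' @param n_steps Time-grid intervals per cycle (>= 50).
#' @param anatomy Anatomy model; defaults to the calibrated default for the
#'   requested side.
#' @param curves Optional named list of [food_curve()] objects overriding
#'   the defaults.
#' @param mode Negative-force policy, see [solve_step()].
#' @return A `chew_simulation`: per-food results (`$foods`, each with
#'   `curve`, `path`, `trajectory`, `solution`, `metrics`), the combined
#'   `metrics` tibble, `proportionality` coefficients and `asymmetry`
#'   summaries.
#' @examples
#' \donttest{
#' sim <- simulate_chewing("d", n_steps = 60)
#' sim$metrics
#' }
#' @export
simulate_chewing <- function(food_ids = FOOD_IDS,
                             working_side = c("right", "left"),
                             v_t = 0.02, n_steps = 200,
                             anatomy = NULL, curves = NULL,
                             mode = c("validation", "exploratory")) {
  working_side <- match.arg(working_side)
  mode <- match.arg(mode)
  anatomy <- anatomy %||% build_default_anatomy(working_side)
  foods <- list()
  for (f in food_ids) {
    curve <- curves[[f]] %||% food_curve(f)
    path <- make_path(f,
      v_t = v_t, working_side = working_side, rho = anatomy$path_rho
    )
    traj <- run_ik(anatomy, path, n_steps = n_steps)
    sol <- augment_temporalis(run_forces(anatomy, traj, curve, mode = mode))
    traj <- attach_forces(traj, sol)
    metrics <- summarize_metrics(sol, traj, anatomy)
    foods[[f]] <- list(
      curve = curve, path = path, trajectory = traj, solution = sol,
      metrics = metrics
    )
  }
  metrics <- dplyr::bind_rows(lapply(foods, `[[`, "metrics"))
  prop <- if (length(food_ids) >= 1) {
    fmax <- tibble::tibble(
      food = food_ids,
      F_max_N = vapply(foods, function(x) x$curve$F_peak, numeric(1)),
      h_m = vapply(foods, function(x) x$path$h, numeric(1))
    )
    proportionality(metrics, fmax)
  } else {
    NULL
  }
  asym <- if (setequal(food_ids, FOOD_IDS)) side_asymmetry(metrics) else NULL
  structure(
    list(
      foods = foods, metrics = metrics, proportionality = prop,
      asymmetry = asym, working_side = working_side,
      v_t = v_t, n_steps = n_steps, anatomy = anatomy
    ),
    class = "chew_simulation"
  )
}

#' @export
print.chew_simulation <- function(x, ...) {
  cat(sprintf(
    "<chew_simulation> foods: %s; working side %s; %d steps\n",
    paste(names(x$foods), collapse = ", "), x$working_side, x$n_steps
  ))
  peaks <- vapply(x$foods, function(f) max(f$solution$series$FM_W_N), numeric(1))
  cat(
    " peak working masseter force (N):",
    paste(sprintf("%s=%.1f", names(peaks), peaks), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Validate the pipeline against the bundled reference set
#'
#' Two validation tiers. The fixture tier recomputes pure-arithmetic
#' quantities (intrinsic strength from forces and PCSA, pooled side
#' deficits, stiffness texture grouping, contraction proportionality)
#' directly from the bundled reference tables - it does not involve the
#' geometry reconstruction. The simulation tier runs the pipeline on the
#' calibrated default anatomy and compares its headline outputs (peak
#' working masseter force over peak occlusal force for dark chocolate,
#' non-working condylar path length for sausage, FM/FMP ratio) with the
#' reference values.
#'
#' @param sim Optional precomputed [simulate_chewing()] result covering all
#'   five foods (saves rerunning the simulation tier).
#' @param n_steps Time steps for the simulation tier when `sim` is `NULL`.
#' @return A tibble with columns `tier`, `check`, `value`, `reference`,
#'   `rel_err`, `tol`, `pass`.
#' @export
validate_model <- function(sim = NULL, n_steps = 200) {
  ref <- reference_metrics_table()
  checks <- list()
  add <- function(tier, check, value, reference, tol) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      tier = tier, check = check, value = value, reference = reference,
      rel_err = (value - reference) / reference, tol = tol,
      pass = abs(value - reference) <= tol * abs(reference)
    )
  }

  # fixture tier
  k_calc <- ref[ref$muscle %in% MUSCLES, ]
  k_diff <- abs(k_calc$F_H_N / k_calc$pcsa_m2 - k_calc$k_N_per_m2)
  # printed precision is one decimal x 1e4 N/m^2, with occasional one-unit
  # slack in the last digit of the largest entries
  k_ok <- k_diff <= pmax(0.05e4, 0.003 * k_calc$k_N_per_m2)
  k_err <- max(k_diff / k_calc$k_N_per_m2)
  add("fixture", "intrinsic_strength_arithmetic_max_rel_err", k_err, 0, Inf)
  checks[[length(checks)]]$pass <- all(k_ok)
  checks[[length(checks)]]$rel_err <- k_err

  asym <- side_asymmetry(ref)
  aval <- function(m) asym$value[asym$metric == m]
  add("fixture", "pooled_force_deficit_pct", aval("force_deficit_pct"), 14, 0.05)
  add("fixture", "pooled_contraction_deficit_pct", aval("contraction_deficit_pct"), 17, 0.05)
  add("fixture", "stiffness_deficit_pct", aval("stiffness_deficit_pct"), 29, 0.05)
  add("fixture", "stiffness_group_ratio", aval("stiffness_group_ratio"), 2.7, 0.05)
  add("fixture", "strength_mp_deficit_pct", aval("strength_mp_deficit_pct"), 28, 0.05)
  add("fixture", "force_mp_deficit_pct", aval("force_mp_deficit_pct"), 10, 0.06)
  prop <- proportionality(ref)
  rqw_m <- prop$R_q[prop$muscle == "masseter" & prop$side == "working"]
  add("fixture", "R_qW_masseter", rqw_m, 0.46, 0.01)
  ts <- split_temporalis(46.1)
  add("fixture", "temporalis_component_sum_N", ts$FAT_N + ts$FMT_N + ts$FPT_N, 46.1, 1e-9)

  # simulation tier
  sim <- sim %||% simulate_chewing(n_steps = n_steps)
  sol_d <- sim$foods$d$solution
  add(
    "simulation", "peak_FM_W_over_peak_F_chocolate",
    max(sol_d$series$FM_W_N) / max(sol_d$series$F_N), 1.215, 0.01
  )
  add(
    "simulation", "condylar_path_N_sausage_m",
    sim$foods$s$trajectory$dd[["non_working"]], 0.0102, 0.02
  )
  add(
    "simulation", "FM_over_FMP_ratio",
    sim$foods$d$solution$split[["masseter"]] /
      sim$foods$d$solution$split[["medial_pterygoid"]], 1.215 / 1.089, 0.01
  )
  add(
    "simulation", "peak_FM_W_carrot_N",
    max(sim$foods$c$solution$series$FM_W_N), 274.3, 0.02
  )
  dplyr::bind_rows(checks)
}
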