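# Calibration of the free geometric parameters.
#
# The skull and mandible the reference coefficients were produced with are
# not distributable, so the landmark surrogate has free parameters:
# attachment positions and line directions within anatomical bounds, the
# guide-plane slopes, the intercondylar half-width and the chewing-path
# start-offset fraction. Calibration tunes them by least squares so that
# the full pipeline reproduces the reference coefficients:
# the six case-I force ratios R_F, the six case-I contraction ratios R_q,
# the non-working condylar path length for sausage, and the food-invariant
# FM / FMP peak-force ratio. The shipped DEFAULT_ANATOMY_PARAMS are the
# converged values, so build_default_anatomy() is pre-calibrated.

CALIBRATION_TARGET_NAMES <- c(
  "force_ratios", "contraction_ratios", "condylar_path", "fm_fmp_ratio",
  "ratio_constancy", "arc_factor"
)

RF_TARGETS <- c(
  FM_W = 1.215, FMP_W = 1.089, FT_W = 0.239,
  FM_N = 1.042, FMP_N = 0.934, FT_N = 0.204
)
RQ_TARGETS <- c(
  masseter_W = 0.46, medial_pterygoid_W = 0.29, temporalis_W = 0.74,
  masseter_N = 0.55, medial_pterygoid_N = 0.36, temporalis_N = 0.90
)
DD_N_SAUSAGE <- 0.0102
FM_FMP_RATIO <- 1.215 / 1.089 # food-invariant peak-force ratio, about 1.116

# Default free parameters: everything that shapes the kinematics and the
# force distribution, keeping the anterior landmarks (IS, IW) and the PCSA
# constants fixed.
CALIBRATION_FREE_PARAMS <- c(
  "cond_y", "guide_psi", "guide_mu", "wcontact_kappa", "wcontact_lat",
  "wcontact_dx", "wcontact_dy", "wcontact_dz",
  "m_ins_x", "m_ins_y", "m_ins_z", "m_tilt", "m_lat",
  "p_ins_x", "p_ins_y", "p_ins_z", "p_tilt", "p_lat",
  "t_ins_x", "t_ins_y", "t_ins_z", "t_tilt",
  "v_dx", "v_dy", "v_dz", "v_tilt", "v_lat",
  "path_rho"
)

CALIBRATION_LOWER <- c(
  cond_y = 0.028, guide_psi = 10, guide_mu = -40, wcontact_kappa = -65,
  wcontact_lat = -35, wcontact_dx = -0.022, wcontact_dy = -0.022, wcontact_dz = -0.022,
  m_ins_x = -0.092, m_ins_y = -0.060, m_ins_z = -0.040, m_tilt = 0, m_lat = -35,
  p_ins_x = -0.092, p_ins_y = -0.055, p_ins_z = -0.050, p_tilt = -20, p_lat = -35,
  t_ins_x = -0.060, t_ins_y = -0.060, t_ins_z = -0.020, t_tilt = -60,
  v_ins_x = -0.094, v_ins_y = -0.060, v_ins_z = -0.040, v_tilt = -25, v_lat = -35,
  path_rho = 0.05
)
CALIBRATION_UPPER <- c(
  cond_y = 0.080, guide_psi = 75, guide_mu = 45, wcontact_kappa = 65,
  wcontact_lat = 35, wcontact_dx = 0.022, wcontact_dy = 0.022, wcontact_dz = 0.022,
  m_ins_x = -0.050, m_ins_y = -0.015, m_ins_z = 0.010, m_tilt = 50, m_lat = 35,
  p_ins_x = -0.050, p_ins_y = -0.010, p_ins_z = 0.010, p_tilt = 40, p_lat = 35,
  t_ins_x = -0.005, t_ins_y = -0.015, t_ins_z = 0.030, t_tilt = -5,
  v_dx = 0.015, v_dy = 0.015, v_dz = 0.015, v_tilt = 40, v_lat = 35,
  path_rho = 0.95
)

# Equilibrium force ratios (per unit occlusal force) at one pose, without
# the sign policing of solve_step: used inside calibration loops.
step_force_ratios <- function(anatomy, pose) {
  g <- step_geometry(anatomy, pose)
  C <- rbind(
    wrench(g$contacts$working$p, g$contacts$working$n),
    wrench(g$contacts$non_working$p, g$contacts$non_working$n)
  )
  Z <- svd(C, nu = 0, nv = 6)$v[, 3:6, drop = FALSE]
  f <- drop(solve(t(Z) %*% g$W_mus, -t(Z) %*% g$w_food))
  stats::setNames(f, c("FT_W", "FT_N", "FV_W", "FV_N"))
}

# Time on the closing arc at which the food force peaks (closure reaches
# p_peak * h): invert the vertical coordinate of the arc, then the
# arc-length parameterisation.
peak_time <- function(path, p_peak) {
  u_peak <- acos(1 - 2 * p_peak) / pi
  s <- path$dense$s_m[findInterval(u_peak, path$dense$u)]
  # refine by local interpolation
  s <- stats::approx(path$dense$u, path$dense$s_m, xout = u_peak)$y
  s / path$v_t
}

# Per-food state entering the calibration residuals: contraction ratios at
# the open pose and force ratios at the peak pose.
calibration_state <- function(anatomy, food_id, v_t = 0.02,
                              n_steps_dd = 100) {
  food <- food_specimen(food_id)
  path <- make_path(food,
    v_t = v_t, working_side = anatomy$working_side,
    rho = anatomy$path_rho, n_dense = 500
  )
  pose_open <- solve_pose(anatomy, path, 0)
  rq <- c()
  for (m in MUSCLES) {
    for (s in SIDES) {
      code <- side_code(s)
      q_open <- muscle_length(anatomy, m, s, pose_open)
      q_rest <- muscle_length(anatomy, m, s, NULL)
      rq[paste0(m, "_", code)] <- (q_open - q_rest) / food$h_m
    }
  }
  p_peak <- default_peak_fraction(food_id)
  pose_peak <- solve_pose(anatomy, path, peak_time(path, p_peak),
    warm_start = pose_open
  )
  fr <- step_force_ratios(anatomy, pose_peak)
  sc <- split_constants(anatomy)
  rf <- c(
    FM_W = sc[["masseter"]] * fr[["FV_W"]],
    FMP_W = sc[["medial_pterygoid"]] * fr[["FV_W"]],
    FT_W = fr[["FT_W"]],
    FM_N = sc[["masseter"]] * fr[["FV_N"]],
    FMP_N = sc[["medial_pterygoid"]] * fr[["FV_N"]],
    FT_N = fr[["FT_N"]]
  )
  dd_n <- NA_real_
  if (food_id == "s") {
    traj <- run_ik(anatomy, path, n_steps = n_steps_dd)
    dd_n <- traj$dd[["non_working"]]
  }
  list(
    rq = rq, rf = rf, dd_n = dd_n,
    arc_factor_err = path$arc_length / (v_t * food$t_chew_s) - 1
  )
}

#' Calibration residuals of an anatomy model
#'
#' Evaluates, per requested target, the scaled residuals of the pipeline
#' against the reference coefficients. Used by [calibrate_anatomy()] and
#' useful on its own as a model health check.
#'
#' @param anatomy An `anatomy_model`.
#' @param targets Character vector of target names (see
#'   [calibrate_anatomy()]).
#' @param n_steps_dd Time steps used for the condylar-path target.
#' @return Named numeric vector of residuals (dimensionless).
#' @export
calibration_residuals <- function(anatomy,
                                  targets = c(
                                    "force_ratios", "contraction_ratios",
                                    "condylar_path", "fm_fmp_ratio"
                                  ),
                                  n_steps_dd = 100) {
  targets <- match.arg(targets, CALIBRATION_TARGET_NAMES, several.ok = TRUE)
  if (length(targets) == 0) {
    return(numeric(0))
  }
  need_states <- any(targets %in% c(
    "force_ratios", "contraction_ratios", "condylar_path",
    "ratio_constancy", "arc_factor"
  ))
  states <- NULL
  if (need_states) {
    states <- lapply(FOOD_IDS, function(f) {
      calibration_state(anatomy, f, n_steps_dd = n_steps_dd)
    })
    names(states) <- FOOD_IDS
  }
  res <- c()
  if ("force_ratios" %in% targets) {
    rf <- rowMeans(sapply(states, `[[`, "rf"))[names(RF_TARGETS)]
    res <- c(res, stats::setNames(
      (rf - RF_TARGETS) / RF_TARGETS, paste0("RF_", names(RF_TARGETS))
    ))
  }
  if ("contraction_ratios" %in% targets) {
    rq <- rowMeans(sapply(states, `[[`, "rq"))[names(RQ_TARGETS)]
    res <- c(res, stats::setNames(
      rq - RQ_TARGETS, paste0("RQ_", names(RQ_TARGETS))
    ))
  }
  if ("condylar_path" %in% targets) {
    res <- c(res, dd_N_sausage = states$s$dd_n / DD_N_SAUSAGE - 1)
  }
  if ("fm_fmp_ratio" %in% targets) {
    sc <- split_constants(anatomy)
    res <- c(
      res,
      fm_fmp_ratio = sc[["masseter"]] / sc[["medial_pterygoid"]] / FM_FMP_RATIO - 1
    )
  }
  if ("ratio_constancy" %in% targets) {
    cv <- function(m) apply(m, 1, function(x) stats::sd(x) / mean(x))
    res <- c(
      res,
      stats::setNames(
        cv(sapply(states, `[[`, "rf"))[names(RF_TARGETS)],
        paste0("CV_RF_", names(RF_TARGETS))
      ),
      stats::setNames(
        cv(sapply(states, `[[`, "rq"))[names(RQ_TARGETS)],
        paste0("CV_RQ_", names(RQ_TARGETS))
      )
    )
  }
  if ("arc_factor" %in% targets) {
    res <- c(res, stats::setNames(
      vapply(states, `[[`, numeric(1), "arc_factor_err"),
      paste0("arc_factor_", FOOD_IDS)
    ))
  }
  res
}

default_calibration_tolerances <- function() {
  c(
    force_ratios = 0.01, # relative, reference "within 1 %"
    contraction_ratios = 0.01, # absolute on R_q, reference "within 0.01"
    condylar_path = 0.02, # relative
    fm_fmp_ratio = 0.01, # relative
    ratio_constancy = 0.02, # CV bound
    arc_factor = 0.01
  )
}

#' Calibrate the free geometric parameters of an anatomy model
#'
#' Least-squares adjustment (Levenberg-Marquardt, [minpack.lm::nls.lm()])
#' of the free parameters so that the simulated pipeline reproduces the
#' selected reference targets. Supported targets: `"force_ratios"` (the six
#' case-I R_F coefficients), `"contraction_ratios"` (the six case-I R_q
#' coefficients), `"condylar_path"` (non-working condylar path length for
#' sausage), `"fm_fmp_ratio"` (the food-invariant masseter / medial
#' pterygoid peak-force ratio), `"ratio_constancy"` (across-food
#' coefficients of variation of R_F and R_q) and `"arc_factor"` (closing
#' arc length over `v_t t_chew`; zero by construction of the path).
#'
#' The model is updated only if every residual is within its tolerance at
#' the optimum; otherwise the input model is returned unchanged with
#' `converged = FALSE`.
#'
#' @param model An `anatomy_model` to start from.
#' @param targets Character vector of target names; an empty vector is the
#'   identity calibration (zero residuals).
#' @param tolerances Named numeric tolerances per target class; defaults
#'   follow the reference agreement levels (1 % on R_F, 0.01 absolute on
#'   R_q, 2 % on the condylar path).
#' @param free_params Parameter names allowed to move.
#' @param max_iter Levenberg-Marquardt iteration budget; `0` evaluates the
#'   residuals without moving the model.
#' @param n_steps_dd Time steps for the condylar-path target.
#' @return A list of class `calibration_report`: `model`, `report` (tibble
#'   of residuals, tolerances and pass flags), `converged`, `params`.
#' @export
calibrate_anatomy <- function(model,
                              targets = c(
                                "force_ratios", "contraction_ratios",
                                "condylar_path", "fm_fmp_ratio"
                              ),
                              tolerances = default_calibration_tolerances(),
                              free_params = CALIBRATION_FREE_PARAMS,
                              max_iter = 25,
                              n_steps_dd = 100) {
  stopifnot(inherits(model, "anatomy_model"))
  if (length(targets) == 0) {
    report <- tibble::tibble(
      target = character(), residual = numeric(), tolerance = numeric(),
      pass = logical()
    )
    return(structure(
      list(model = model, report = report, converged = TRUE, params = model$params),
      class = "calibration_report"
    ))
  }
  targets <- match.arg(targets, CALIBRATION_TARGET_NAMES, several.ok = TRUE)
  tol_full <- default_calibration_tolerances()
  tol_full[names(tolerances)] <- tolerances

  side <- model$working_side
  par0 <- model$params[free_params]
  resid_fn <- function(par) {
    m <- tryCatch(
      anatomy_from_params(
        replace(model$params, free_params, par),
        working_side = side, pcsa = model$pcsa
      ),
      error = function(e) NULL
    )
    if (is.null(m)) {
      return(rep(10, 30))
    }
    tryCatch(
      calibration_residuals(m, targets, n_steps_dd = n_steps_dd),
      error = function(e) rep(10, 30)
    )
  }

  par_opt <- par0
  if (max_iter > 0) {
    fit <- minpack.lm::nls.lm(
      par = par0, fn = resid_fn,
      lower = CALIBRATION_LOWER[free_params],
      upper = CALIBRATION_UPPER[free_params],
      control = minpack.lm::nls.lm.control(maxiter = max_iter)
    )
    par_opt <- fit$par
  }
  res <- resid_fn(par_opt)

  tol_of <- function(nm) {
    cls <- dplyr::case_when(
      grepl("^RF_", nm) ~ "force_ratios",
      grepl("^RQ_", nm) ~ "contraction_ratios",
      grepl("^CV_", nm) ~ "ratio_constancy",
      grepl("^dd_", nm) ~ "condylar_path",
      grepl("^fm_", nm) ~ "fm_fmp_ratio",
      TRUE ~ "arc_factor"
    )
    unname(tol_full[cls])
  }
  report <- tibble::tibble(
    target = names(res),
    residual = unname(res),
    tolerance = tol_of(names(res)),
    pass = abs(unname(res)) <= tol_of(names(res))
  )
  converged <- all(report$pass)
  new_params <- replace(model$params, free_params, par_opt)
  out_model <- if (converged) {
    anatomy_from_params(new_params, working_side = side, pcsa = model$pcsa)
  } else {
    model
  }
  structure(
    list(
      model = out_model, report = report, converged = converged,
      params = new_params
    ),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    "<calibration_report> converged: %s (%d/%d residuals within tolerance)\n",
    x$converged, sum(x$report$pass), nrow(x$report)
  ))
  worst <- x$report[order(-abs(x$report$residual)), ]
  print(utils::head(worst, 5))
  invisible(x)
}
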