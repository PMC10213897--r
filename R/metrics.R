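# Derived muscle parameters: maxima, contractions, stiffness, intrinsic
# strength, proportionality coefficients and side-asymmetry summaries.

metric_muscles <- function() c(MUSCLES, TEMPORALIS_PARTS)

part_pcsa <- function(pcsa) {
  f <- TEMPORALIS_FRACTIONS
  c(
    anterior_temporalis = f[["anterior"]] * pcsa[["temporalis"]],
    middle_temporalis = f[["middle"]] * pcsa[["temporalis"]],
    posterior_temporalis = f[["posterior"]] * pcsa[["temporalis"]]
  )
}

#' Summarise a simulation into a per-muscle metrics table
#'
#' For every muscle (three principals and the three temporalis parts) and
#' side, extracts the maximum force `F_H` over the closing phase, its time
#' `t_H`, the contraction at maximum force `dq_H`, the total contraction
#' `dq_C`, the secant stiffness `K = F_H / dq_H` and the intrinsic strength
#' `k = F_H / PCSA` (temporalis parts use their PCSA-proportional share, so
#' their `k` equals the principal's).
#'
#' @param solution A [run_forces()] solution.
#' @param trajectory The matching [run_ik()] trajectory.
#' @param anatomy The `anatomy_model` used (PCSA source); defaults to the
#'   trajectory's.
#' @param food Food id used to label rows; defaults to the trajectory's.
#' @return A tibble with one row per (food, side, muscle); rows whose force
#'   series is all zero are flagged `defined = FALSE` and carry no `K`/`k`.
#' @export
summarize_metrics <- function(solution, trajectory, anatomy = NULL,
                              food = NULL) {
  stopifnot(
    inherits(solution, "muscle_force_solution"),
    inherits(trajectory, "mandible_trajectory")
  )
  if (!identical(solution$food_id, trajectory$path$food_id)) {
    stop_chewsim("solution and trajectory refer to different foods")
  }
  anatomy <- anatomy %||% trajectory$anatomy
  food <- food %||% trajectory$path$food_id
  solution <- augment_temporalis(solution)
  pcsa <- c(anatomy$pcsa, part_pcsa(anatomy$pcsa))

  rows <- list()
  for (m in metric_muscles()) {
    for (s in SIDES) {
      fcol <- force_column(m, s)
      Fser <- solution$series[[fcol]]
      defined <- any(Fser > 0)
      i_h <- which.max(Fser)
      F_H <- Fser[i_h]
      t_H <- solution$series$t_s[i_h]
      dq_C <- contraction(trajectory, m, s, kind = "total")
      dq_H <- if (defined) {
        contraction(trajectory, m, s, kind = "at_time", t_ref = t_H)
      } else {
        NA_real_
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        food = food, side = s, muscle = m,
        F_H_N = F_H, t_H_s = if (defined) t_H else NA_real_,
        dq_H_m = dq_H, dq_C_m = dq_C,
        K_N_per_m = if (defined) F_H / dq_H else NA_real_,
        k_N_per_m2 = if (defined) F_H / pcsa[[m]] else NA_real_,
        defined = defined
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Reference tables joined into one metrics table
#'
#' Combines the bundled reference forces/contractions, stiffness and
#' intrinsic strength into the same shape as [summarize_metrics()] output,
#' for fixture-level arithmetic checks that do not involve the simulation.
#'
#' @return A tibble with one row per (food, side, muscle).
#' @export
reference_metrics_table <- function() {
  forces <- reference_table("max_forces_contractions")
  stiff <- reference_table("stiffness")
  strength <- reference_table("intrinsic_strength")
  out <- dplyr::left_join(forces, stiff, by = c("food", "side", "muscle"))
  out <- dplyr::left_join(
    out, strength[, c("food", "side", "muscle", "pcsa_m2", "k_N_per_m2")],
    by = c("food", "side", "muscle")
  )
  dplyr::mutate(out, defined = TRUE)
}

#' Force and contraction proportionality coefficients
#'
#' Per muscle and side, the mean over foods of `R_F = F_H / F_max` and
#' `R_q = dq_C / h`, with their across-food coefficients of variation. With
#' a single food whose `F_max` was itself obtained by inverting the
#' `F_H = R_F F_max` relation, the returned `R_F` reproduces the inversion
#' input exactly (a circular identity; at least two foods are needed for an
#' informative constancy check).
#'
#' @param table A metrics table ([summarize_metrics()] rows, possibly
#'   several foods bound together, or [reference_metrics_table()]).
#' @param foods A tibble with columns `food`, `F_max_N`, `h_m`; defaults to
#'   the catalogue heights and the default peak forces.
#' @return A tibble per (muscle, side) with `R_F`, `R_F_cv`, `R_q`,
#'   `R_q_cv`, `n_foods`.
#' @export
proportionality <- function(table, foods = NULL) {
  if (is.null(foods)) {
    cat <- food_catalog()
    foods <- tibble::tibble(
      food = cat$id,
      F_max_N = vapply(cat$id, default_peak_force, numeric(1)),
      h_m = cat$h_m
    )
  }
  if (any(foods$F_max_N <= 0) || any(foods$h_m <= 0)) {
    stop_chewsim("F_max and h must be positive for every food")
  }
  joined <- dplyr::inner_join(table, foods, by = "food")
  if (nrow(joined) == 0) stop_chewsim("no foods in common between table and foods")
  cv <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / mean(x)
  joined |>
    dplyr::mutate(
      rf = .data$F_H_N / .data$F_max_N,
      rq = .data$dq_C_m / .data$h_m
    ) |>
    dplyr::group_by(.data$muscle, .data$side) |>
    dplyr::summarise(
      R_F = mean(.data$rf), R_F_cv = cv(.data$rf),
      R_q = mean(.data$rq), R_q_cv = cv(.data$rq),
      n_foods = dplyr::n(), .groups = "drop"
    )
}

#' Side-asymmetry summaries
#'
#' Pooled and per-case asymmetry measures between the working and
#' non-working sides and between masseter and medial pterygoid:
#' \describe{
#'   \item{force_deficit_pct}{pooled over the three principal muscles and
#'     all foods: `100 (1 - sum F_HN / sum F_HW)`.}
#'   \item{contraction_deficit_pct}{pooled: `100 (1 - sum dq_CW / sum
#'     dq_CN)` (the working side contracts less in total).}
#'   \item{stiffness_deficit_pct}{mean per (muscle, food) case of
#'     `100 (1 - K_N / K_W)`, all muscles with stiffness values.}
#'   \item{stiffness_group_ratio}{mean over (muscle, side) of the mean
#'     stiffness of the hard-texture group (d, c) over the mean of the
#'     soft group (b, a, s).}
#'   \item{strength_mp_deficit_pct}{mean per-case percentage by which the
#'     masseter's intrinsic strength falls short of the medial
#'     pterygoid's.}
#'   \item{force_mp_deficit_pct}{mean per-case percentage by which the
#'     medial pterygoid's maximum force falls short of the masseter's.}
#' }
#'
#' @param table A metrics table covering both sides, the three principal
#'   muscles and the five foods (temporalis parts are used where present).
#' @return A tibble with columns `metric`, `value`.
#' @export
side_asymmetry <- function(table) {
  needed <- expand.grid(
    food = FOOD_IDS, side = SIDES, muscle = MUSCLES,
    stringsAsFactors = FALSE
  )
  have <- unique(table[, c("food", "side", "muscle")])
  missing <- dplyr::anti_join(needed, have, by = c("food", "side", "muscle"))
  if (nrow(missing) > 0) {
    stop_chewsim(
      "incomplete metrics table; missing cells: ",
      paste(
        utils::head(
          sprintf("%s/%s/%s", missing$food, missing$side, missing$muscle), 10
        ),
        collapse = ", "
      )
    )
  }
  principal <- table[table$muscle %in% MUSCLES, ]
  w <- principal[principal$side == "working", ]
  n <- principal[principal$side == "non_working", ]

  force_deficit <- 100 * (1 - sum(n$F_H_N) / sum(w$F_H_N))
  contraction_deficit <- 100 * (1 - sum(w$dq_C_m) / sum(n$dq_C_m))

  wide <- tidyr::pivot_wider(
    table[, c("food", "side", "muscle", "F_H_N", "K_N_per_m", "k_N_per_m2")],
    names_from = "side",
    values_from = c("F_H_N", "K_N_per_m", "k_N_per_m2")
  )
  kk <- wide[!is.na(wide$K_N_per_m_working) & !is.na(wide$K_N_per_m_non_working), ]
  stiffness_deficit <-
    mean(100 * (1 - kk$K_N_per_m_non_working / kk$K_N_per_m_working))

  hard <- c("d", "c")
  kgroups <- table[!is.na(table$K_N_per_m), ] |>
    dplyr::group_by(.data$muscle, .data$side) |>
    dplyr::summarise(
      ratio = mean(.data$K_N_per_m[.data$food %in% hard]) /
        mean(.data$K_N_per_m[!.data$food %in% hard]),
      .groups = "drop"
    )
  stiffness_group_ratio <- mean(kgroups$ratio)

  per_case <- function(col, num, den) {
    x <- tidyr::pivot_wider(
      table[table$muscle %in% c(num, den), c("food", "side", "muscle", col)],
      names_from = "muscle", values_from = dplyr::all_of(col)
    )
    mean(100 * (1 - x[[num]] / x[[den]]))
  }
  strength_mp <- per_case("k_N_per_m2", "masseter", "medial_pterygoid")
  force_mp <- per_case("F_H_N", "medial_pterygoid", "masseter")

  tibble::tibble(
    metric = c(
      "force_deficit_pct", "contraction_deficit_pct",
      "stiffness_deficit_pct", "stiffness_group_ratio",
      "strength_mp_deficit_pct", "force_mp_deficit_pct"
    ),
    value = c(
      force_deficit, contraction_deficit, stiffness_deficit,
      stiffness_group_ratio, strength_mp, force_mp
    )
  )
}

#' Fit a monotone stiffness function to force-contraction samples
#'
#' Monotone piecewise-cubic fit of force versus contraction on the rising
#' limb; the tangent stiffness is its derivative. With `smoothing > 0` the
#' samples are first smoothed with a smoothing spline. If the (smoothed)
#' samples are still materially non-monotone the fit errors; minuscule
#' reversals are clamped and, should the monotone interpolant be
#' unavailable, a central-difference derivative is used as fallback.
#'
#' @param dq Contraction samples, m, increasing.
#' @param F Force samples, N.
#' @param smoothing Smoothing parameter passed to
#'   [stats::smooth.spline()]'s `spar` (0 = interpolate the samples).
#' @return An object of class `stiffness_function`: callable pieces
#'   `value(dq)` (N) and `K(dq)` (N/m).
#' @export
stiffness_fit <- function(dq, F, smoothing = 0) {
  stopifnot(length(dq) == length(F))
  ord <- order(dq)
  dq <- dq[ord]
  F <- F[ord]
  keep <- c(TRUE, diff(dq) > 1e-12)
  dq <- dq[keep]
  F <- F[keep]
  if (length(dq) < 20) {
    stop_chewsim("need at least 20 samples on the rising limb, got ", length(dq))
  }
  if (smoothing > 0) {
    ss <- stats::smooth.spline(dq, F, spar = smoothing)
    F <- stats::predict(ss, dq)$y
  }
  drop_tol <- 1e-3 * max(abs(F))
  if (any(diff(F) < -drop_tol)) {
    stop_chewsim("non-monotone rising limb after smoothing; cannot fit")
  }
  F <- cummax(F) # clamp numerically tiny reversals
  fit <- tryCatch(
    stats::splinefun(dq, F, method = "hyman"),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    value <- stats::approxfun(dq, F, rule = 2)
    Kgrid <- c(
      diff(F[1:2]) / diff(dq[1:2]),
      (F[-(1:2)] - F[1:(length(F) - 2)]) / (dq[-(1:2)] - dq[1:(length(dq) - 2)]),
      diff(F[length(F) - 1:0])[1] / diff(dq[length(dq) - 1:0])[1]
    )
    K <- stats::approxfun(dq, Kgrid, rule = 2)
  } else {
    value <- fit
    K <- function(x) fit(x, deriv = 1)
  }
  structure(
    list(value = value, K = K, dq_range = range(dq)),
    class = "stiffness_function"
  )
}

#' Non-linear stiffness of a muscle from a simulation
#'
#' Extracts the rising limb (start of loading to the force maximum) of a
#' muscle's force-contraction pattern and fits the monotone stiffness
#' function; reports the tangent stiffness at `dq_H` next to the secant
#' value `F_H / dq_H` (a tangent-vs-secant gap of order 10 % is expected
#' for these concave patterns).
#'
#' @param solution A [run_forces()] solution.
#' @param trajectory The matching trajectory.
#' @param muscle,side Muscle line selector.
#' @param smoothing See [stiffness_fit()].
#' @return A `stiffness_function` with extra fields `dq_H`, `K_secant`,
#'   `K_tangent_at_H`, `secant_gap` (relative difference).
#' @export
stiffness_function <- function(solution, trajectory, muscle,
                               side = SIDES, smoothing = 0) {
  side <- match.arg(side)
  solution <- augment_temporalis(solution)
  fcol <- force_column(muscle, side)
  F <- solution$series[[fcol]]
  qcol <- paste0("q_", muscle, "_", side_code(side), "_m")
  dq <- trajectory$q[[qcol]][1] - trajectory$q[[qcol]]
  i_h <- which.max(F)
  if (i_h < 2 || F[i_h] <= 0) stop_chewsim("force series has no rising limb")
  idx <- seq_len(i_h)
  out <- stiffness_fit(dq[idx], F[idx], smoothing = smoothing)
  out$dq_H <- dq[i_h]
  out$K_secant <- F[i_h] / dq[i_h]
  out$K_tangent_at_H <- out$K(dq[i_h])
  out$secant_gap <- abs(out$K_tangent_at_H - out$K_secant) / out$K_secant
  out
}

#' @export
print.stiffness_function <- function(x, ...) {
  cat(sprintf(
    "<stiffness_function> on dq in [%.2g, %.2g] mm",
    1000 * x$dq_range[1], 1000 * x$dq_range[2]
  ))
  if (!is.null(x$K_secant)) {
    cat(sprintf(
      "; K(dq_H) = %.3g N/m vs secant %.3g N/m (gap %.1f %%)",
      x$K_tangent_at_H, x$K_secant, 100 * x$secant_gap
    ))
  }
  cat("\n")
  invisible(x)
}
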