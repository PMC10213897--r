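# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

muscle_from_code <- function(code) {
  c(
    FM = "masseter", FMP = "medial_pterygoid", FT = "temporalis",
    FV = "resultant_v", FAT = "anterior_temporalis",
    FMT = "middle_temporalis", FPT = "posterior_temporalis"
  )[code]
}
side_from_code <- function(code) c(W = "working", N = "non_working")[code]

#' Tidy a mandible trajectory into a long tibble
#'
#' @param x A [run_ik()] result.
#' @param ... Unused.
#' @return A tibble with columns `t_s`, `muscle`, `side`, `q_m`,
#'   `contraction_m` (shortening relative to the open-mouth start).
#' @export
tidy.mandible_trajectory <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(t_s = x$t_s), x$q),
    -"t_s",
    names_to = c("muscle", "side"),
    names_pattern = "^q_(.*)_([WN])_m$",
    values_to = "q_m"
  )
  long$side <- unname(side_from_code(long$side))
  dplyr::mutate(
    dplyr::group_by(long, .data$muscle, .data$side),
    contraction_m = dplyr::first(.data$q_m) - .data$q_m
  ) |> dplyr::ungroup()
}

#' @export
glance.mandible_trajectory <- function(x, ...) {
  tibble::tibble(
    food = x$path$food_id,
    n_steps = x$n_steps,
    t_chew_s = max(x$t_s),
    dd_W_m = x$dd[["working"]],
    dd_N_m = x$dd[["non_working"]],
    max_opening_rad = max(x$pose_tbl$open_rad)
  )
}

#' Tidy a muscle force solution into a long tibble
#'
#' @param x A [run_forces()] result.
#' @param ... Unused.
#' @return A tibble with columns `t_s`, `F_food_N`, `muscle`, `side`,
#'   `force_N`.
#' @export
tidy.muscle_force_solution <- function(x, ...) {
  s <- x$series
  long <- tidyr::pivot_longer(
    s[, c("t_s", setdiff(names(s), c("t_s", "F_N", "R_TMJ_W_N", "R_TMJ_N_N")))],
    -"t_s",
    names_to = c("code", "side"),
    names_pattern = "^(F[A-Z]*)_([WN])_N$",
    values_to = "force_N"
  )
  long$muscle <- unname(muscle_from_code(long$code))
  long$side <- unname(side_from_code(long$side))
  dplyr::left_join(
    long[, c("t_s", "muscle", "side", "force_N")],
    s[, c("t_s", "F_N")],
    by = "t_s"
  ) |>
    dplyr::rename(F_food_N = "F_N")
}

#' @export
glance.muscle_force_solution <- function(x, ...) {
  tibble::tibble(
    food = x$food_id,
    peak_F_N = max(x$series$F_N),
    peak_FM_W_N = max(x$series$FM_W_N),
    peak_FT_W_N = max(x$series$FT_W_N),
    split_masseter = x$split[["masseter"]],
    split_medial_pterygoid = x$split[["medial_pterygoid"]],
    max_equilibrium_residual = x$max_residual,
    max_crosscheck = x$max_crosscheck
  )
}

#' @export
tidy.calibration_report <- function(x, ...) x$report

#' @export
glance.calibration_report <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    n_targets = nrow(x$report),
    n_pass = sum(x$report$pass),
    worst_residual = if (nrow(x$report)) max(abs(x$report$residual)) else 0
  )
}

#' @export
tidy.chew_simulation <- function(x, ...) x$metrics

#' @export
glance.chew_simulation <- function(x, ...) {
  dplyr::bind_rows(lapply(x$foods, function(f) glance(f$solution)))
}

#' Plot a food force-deformation curve
#'
#' @param object A [food_curve()].
#' @param n Number of samples.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.food_curve <- function(object, n = 300, ...) {
  dh <- seq(0, object$food$h_m, length.out = n)
  df <- tibble::tibble(dh_mm = 1000 * dh, F_N = force_at(object, dh))
  ggplot2::ggplot(df, ggplot2::aes(.data$dh_mm, .data$F_N)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "height reduction (mm)", y = "resistance force (N)",
      title = sprintf("%s (%s)", object$food$label, object$shape)
    )
}

#' Plot a chewing path in the frontal plane
#'
#' @param object A [make_path()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chew_path <- function(object, ...) {
  df <- object$dense
  ggplot2::ggplot(df, ggplot2::aes(1000 * .data$y_m, 1000 * .data$z_m)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point",
      x = 1000 * object$BP[["y"]], y = 1000 * object$BP[["z"]]
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "lateral (mm)", y = "vertical (mm)",
      title = sprintf("closing arc, food %s", object$food_id)
    )
}

#' Plot muscle length histories of a trajectory
#'
#' @param object A [run_ik()] result.
#' @param muscles Muscles to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mandible_trajectory <- function(object, muscles = MUSCLES, ...) {
  df <- dplyr::filter(tidy(object), .data$muscle %in% muscles)
  ggplot2::ggplot(df, ggplot2::aes(.data$t_s, 1000 * .data$q_m,
    colour = .data$side
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~muscle, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "muscle length (mm)")
}

#' Plot muscle force patterns (force vs contraction)
#'
#' Reproduces the characteristic muscle-pattern view: force against
#' contraction for each muscle and side over the closing cycle.
#'
#' @param object A [run_forces()] result.
#' @param trajectory The matching [run_ik()] trajectory.
#' @param muscles Muscles to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.muscle_force_solution <- function(object, trajectory,
                                           muscles = MUSCLES, ...) {
  ft <- tidy(object)
  qt <- tidy(trajectory)
  df <- dplyr::inner_join(ft, qt, by = c("t_s", "muscle", "side")) |>
    dplyr::filter(.data$muscle %in% muscles)
  ggplot2::ggplot(df, ggplot2::aes(1000 * .data$contraction_m, .data$force_N,
    colour = .data$side
  )) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~muscle, scales = "free") +
    ggplot2::labs(x = "contraction (mm)", y = "muscle force (N)")
}
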