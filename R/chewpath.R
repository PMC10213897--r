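# Food-dependent chewing path of the incisal point in the frontal plane.
#
# The closing arc is an ellipse-like curve from the chewing start point BP
# (laterally offset toward the working side, a food height h below closure)
# up to the incisal end point IS at the origin. Its vertical extent equals
# the food height exactly and its arc length equals v_t * t_chew, the
# distance travelled at the constant closing speed. Because the reference
# chewing times exceed h / v_t by a consistent factor of about 1.11, the
# lateral amplitude of the arc is solved per food so that the arc-length
# constraint holds exactly.
#
# The lateral profile has two parts controlled by the shape fraction rho:
# a start offset that decays with closure (rho) and a mid-arc bulge beyond
# the BP-IS chord (1 - rho). The start offset swings the mandible toward
# the working side at the open-mouth pose; it is the geometric origin of
# the working / non-working asymmetry of the total muscle contractions.

#' Generate the chewing path for a food
#'
#' Builds the closing arc of the ellipse-like chewing path of the incisal
#' point in the frontal plane (y lateral, z vertical), parameterised
#' uniformly by arc length so that the incisal point moves at the constant
#' closing speed `v_t`.
#'
#' @param food Food id or a one-row tibble from [food_specimen()].
#' @param aspect Optional lateral amplitude as a fraction of the food
#'   height. By default the amplitude is solved so that the closing arc
#'   length equals `v_t * t_chew`.
#' @param v_t Closing speed of the incisal point, m/s.
#' @param working_side `"right"` or `"left"`; the lateral excursion points
#'   toward the working side.
#' @param rho Shape fraction in `[0, 1)` splitting the lateral profile
#'   between the start offset at BP and the mid-arc bulge. Defaults to the
#'   calibrated anatomy value.
#' @param n_dense Number of samples of the dense arc-length table.
#' @return An object of class `chew_path`.
#' @examples
#' path <- make_path("s")
#' path$arc_length / path$h # about 1.11
#' @export
make_path <- function(food, aspect = NULL, v_t = 0.02,
                      working_side = c("right", "left"),
                      rho = DEFAULT_ANATOMY_PARAMS[["path_rho"]],
                      n_dense = 2000) {
  working_side <- match.arg(working_side)
  food <- if (is.data.frame(food)) food else food_specimen(food)
  h <- food$h_m
  t_chew <- food$t_chew_s
  if (!is.finite(h) || h <= 0) stop_chewsim("food height must be positive")
  stopifnot(v_t > 0, t_chew > 0, rho >= 0, rho < 1)
  side_sign <- if (working_side == "right") -1 else 1
  target_len <- v_t * t_chew

  u <- seq(0, 1, length.out = n_dense + 1)
  zu <- -h * (1 + cos(pi * u)) / 2
  lat_profile <- rho * (1 + cos(pi * u)) / 2 + (1 - rho) * sin(pi * u)

  arc_len_for <- function(A) {
    y <- A * lat_profile
    sum(sqrt(diff(y)^2 + diff(zu)^2))
  }
  if (is.null(aspect)) {
    if (target_len <= h * (1 + 1e-9)) {
      stop_chewsim(
        "v_t * t_chew must exceed the food height; got ",
        format(target_len), " vs h = ", format(h)
      )
    }
    A <- stats::uniroot(
      function(A) arc_len_for(A) - target_len,
      interval = c(0, 2 * h), tol = 1e-12
    )$root
  } else {
    stopifnot(aspect > 0)
    A <- aspect * h
  }

  y <- side_sign * A * lat_profile
  seg <- sqrt(diff(y)^2 + diff(zu)^2)
  s <- c(0, cumsum(seg))
  arc_length <- s[length(s)]
  # arc-length -> parameter interpolant (monotone cubic)
  u_of_s <- stats::splinefun(s, u, method = "hyman")

  structure(
    list(
      food = food, food_id = food$id, h = h, t_chew = t_chew, v_t = v_t,
      working_side = working_side, side_sign = side_sign,
      rho = rho, amplitude = A, aspect = A / h,
      BP = c(y = y[1], z = zu[1]),
      arc_length = arc_length,
      u_of_s = u_of_s,
      dense = tibble::tibble(u = u, s_m = s, y_m = y, z_m = zu)
    ),
    class = "chew_path"
  )
}

#' @export
print.chew_path <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<chew_path> food %s, working side %s: height %.1f mm, ",
      "lateral amplitude %.1f mm, closing arc %.1f mm (= v_t * t_chew)\n"
    ),
    x$food_id, x$working_side, 1000 * x$h, 1000 * x$amplitude,
    1000 * x$arc_length
  ))
  invisible(x)
}

path_point_at_u <- function(path, u) {
  h <- path$h
  z <- -h * (1 + cos(pi * u)) / 2
  lat <- path$rho * (1 + cos(pi * u)) / 2 + (1 - path$rho) * sin(pi * u)
  cbind(y_m = path$side_sign * path$amplitude * lat, z_m = z)
}

#' Position on the closing arc at a given time
#'
#' Arc-length-uniform evaluation of the closing arc: the incisal point has
#' travelled `v_t * t` along the arc at time `t`, so its speed is `v_t`
#' everywhere.
#'
#' @param path A [make_path()] object.
#' @param t Time(s) in seconds, in `[0, t_chew]`.
#' @return A tibble with columns `t_s`, `y_m`, `z_m`.
#' @export
closing_position <- function(path, t) {
  stopifnot(inherits(path, "chew_path"))
  if (any(t < -1e-12 | t > path$t_chew + 1e-9)) {
    stop_chewsim(
      "t out of range [0, ", format(path$t_chew), "] s: ",
      paste(format(t[t < -1e-12 | t > path$t_chew + 1e-9]), collapse = ", ")
    )
  }
  t <- pmin(pmax(t, 0), path$t_chew)
  s <- pmin(path$v_t * t, path$arc_length)
  u <- pmin(pmax(path$u_of_s(s), 0), 1)
  pt <- path_point_at_u(path, u)
  tibble::tibble(
    t_s = t, y_m = unname(pt[, "y_m"]), z_m = unname(pt[, "z_m"])
  )
}

#' Closure function of a chewing path
#'
#' Returns the function `dh(t)` mapping time to the reduction of the food
#' height, `dh = h + z(t)` with `z` the vertical coordinate of the incisal
#' point on the closing arc. Composing it with a food curve yields the
#' occlusal force history.
#'
#' @param path A [make_path()] object.
#' @return A function of time returning metres.
#' @export
closure_function <- function(path) {
  force(path)
  function(t) path$h + closing_position(path, t)$z_m
}

#' Full chewing cycle samples
#'
#' The force solve runs on the closing arc only; the opening half of the
#' cycle is generated for completeness as the mirror image of the closing
#' arc through the BP-IS chord, traversed downward.
#'
#' @param path A [make_path()] object.
#' @param n_steps Samples per half cycle.
#' @return A tibble with columns `phase`, `t_s`, `y_m`, `z_m`; opening-phase
#'   times are negative (time to the start of chewing).
#' @export
chew_cycle <- function(path, n_steps = 100) {
  t <- seq(0, path$t_chew, length.out = n_steps + 1)
  closing <- closing_position(path, t)
  u <- seq(1, 0, length.out = n_steps + 1)
  pt <- path_point_at_u(path, u)
  chord_y <- path$BP[["y"]] * (-pt[, "z_m"] / path$h) # chord at this height
  opening <- tibble::tibble(
    t_s = -rev(t),
    y_m = rev(2 * chord_y - pt[, "y_m"]),
    z_m = rev(pt[, "z_m"])
  )
  dplyr::bind_rows(
    dplyr::mutate(opening, phase = "opening"),
    dplyr::mutate(closing, phase = "closing")
  )[, c("phase", "t_s", "y_m", "z_m")]
}

#' Export a chewing path as CSV
#'
#' @param path A [make_path()] object.
#' @param file Output file path.
#' @param n_steps Number of time samples.
#' @return The file path, invisibly.
#' @export
write_path_csv <- function(path, file, n_steps = 200) {
  t <- seq(0, path$t_chew, length.out = n_steps + 1)
  df <- as.data.frame(closing_position(path, t))
  write_csv_commented(
    df, file,
    comment = sprintf(
      "chew path food %s: t_s (s), y_m (m), z_m (m); v_t=%.3g m/s, working side %s",
      path$food_id, path$v_t, path$working_side
    )
  )
  invisible(file)
}
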