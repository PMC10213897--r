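# Stage 1: inverse kinematics of the mandible.
#
# The mandible pose is parameterised by three rotations about the working
# condyle centre (opening about the transverse axis, yaw about the vertical
# axis, roll about the anteroposterior axis). The working condyle is the
# fixed centre of rotation; the non-working condyle is constrained to its
# inclined guide plane. Per time step the incisal point is prescribed on
# the chewing path in the frontal plane, giving a well-posed 3x3 root
# finding problem: two incisal coordinates plus the plane constraint
# determine the three rotation angles. The slide of the non-working condyle
# along the guide plane is recovered from the solved pose.

#' Rigid transform of a mandibular pose
#'
#' Applies the pose rotation about the working condyle centre to one or
#' more mandible-fixed points.
#'
#' @param pose A pose object (fields `open`, `yaw`, `roll` in radians).
#' @param model The `anatomy_model` the pose refers to.
#' @param p A 3-vector or a 3-row matrix of points.
#' @return Transformed point(s), same shape as `p`.
#' @export
pose_transform <- function(pose, model, p) {
  R <- pose_rotation(pose)
  cw <- model$condyle$working
  if (is.matrix(p)) {
    cw + R %*% (p - cw)
  } else {
    drop(cw + R %*% (p - cw))
  }
}

pose_rotation <- function(pose) {
  rot_x(pose$roll) %*% rot_z(pose$yaw) %*% rot_y(pose$open)
}

new_pose <- function(angles, t = NA_real_) {
  structure(
    list(open = angles[1], yaw = angles[2], roll = angles[3], t_s = t),
    class = "mandible_pose"
  )
}

#' @export
print.mandible_pose <- function(x, ...) {
  cat(sprintf(
    "<mandible_pose> t = %.4g s: open %.4f rad, yaw %.4f rad, roll %.4f rad\n",
    x$t_s, x$open, x$yaw, x$roll
  ))
  invisible(x)
}

ik_residual <- function(angles, model, target_yz) {
  pose <- new_pose(angles)
  R <- pose_rotation(pose)
  cw <- model$condyle$working
  is_t <- cw + R %*% (model$IS - cw)
  cn0 <- model$condyle$non_working
  cn_t <- cw + R %*% (cn0 - cw)
  gp <- model$guide_plane_N
  c(
    is_t[2] - target_yz[1],
    is_t[3] - target_yz[2],
    sum(gp$normal * (cn_t - gp$point))
  )
}

#' Solve the mandibular pose at one time step
#'
#' Damped Newton iteration on the three rotation angles: the incisal point
#' must map onto the chewing-path point in the frontal plane and the
#' non-working condyle must stay on its guide plane.
#'
#' @param anatomy An `anatomy_model`.
#' @param path A [make_path()] object.
#' @param t Time in seconds, in `[0, t_chew]`.
#' @param warm_start Optional previous pose used as the starting iterate.
#' @param tol Convergence tolerance on the residual, metres.
#' @param max_iter Maximum Newton iterations.
#' @return A `mandible_pose`.
#' @export
solve_pose <- function(anatomy, path, t, warm_start = NULL,
                       tol = 1e-11, max_iter = 50) {
  target <- closing_position(path, t)
  target_yz <- c(target$y_m, target$z_m)
  x <- if (!is.null(warm_start)) {
    c(warm_start$open, warm_start$yaw, warm_start$roll)
  } else {
    # crude opening guess from the vertical drop of the incisal point
    c(-target$z_m / abs(anatomy$condyle$working[1]), 0, 0)
  }
  r <- ik_residual(x, anatomy, target_yz)
  for (iter in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    J <- matrix(0, 3, 3)
    hstep <- 1e-7
    for (j in 1:3) {
      xp <- x
      xp[j] <- xp[j] + hstep
      xm <- x
      xm[j] <- xm[j] - hstep
      J[, j] <- (ik_residual(xp, anatomy, target_yz) -
        ik_residual(xm, anatomy, target_yz)) / (2 * hstep)
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) {
      stop_chewsim(
        "pose solve singular at t = ", format(t),
        " s (residual ", format(max(abs(r))), " m)"
      )
    }
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      rn <- ik_residual(xn, anatomy, target_yz)
      if (sum(rn^2) < sum(r^2) || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    x <- xn
    r <- rn
  }
  if (max(abs(r)) >= tol) {
    stop_chewsim(
      "pose solve did not converge at t = ", format(t),
      " s; residuals (m): ", paste(format(r, digits = 3), collapse = ", "),
      " - is the path point reachable?"
    )
  }
  new_pose(x, t = t)
}

#' Run the inverse-kinematics stage over one closing cycle
#'
#' Solves the pose on a uniform time grid over the closing arc and records
#' the muscle length series for the principal muscles, the V resultant and
#' the temporalis part lines on both sides, plus the condylar trajectories.
#'
#' @param anatomy An `anatomy_model`.
#' @param path A [make_path()] object.
#' @param n_steps Number of grid intervals (at least 50).
#' @return A `mandible_trajectory`: time grid, poses, muscle length series
#'   `q_<muscle>_<side>_m`, rest lengths, condylar paths and their lengths
#'   `dd` per side.
#' @export
run_ik <- function(anatomy, path, n_steps = 200) {
  if (n_steps < 50) stop_chewsim("n_steps must be at least 50")
  t_grid <- seq(0, path$t_chew, length.out = n_steps + 1)
  n <- length(t_grid)
  muscles <- names(anatomy$muscles)

  poses <- vector("list", n)
  # solve backwards from the closed end: the identity pose at t_chew is a
  # known exact solution and warm starts propagate continuity
  warm <- new_pose(c(0, 0, 0))
  for (i in rev(seq_len(n))) {
    poses[[i]] <- solve_pose(anatomy, path, t_grid[i], warm_start = warm)
    warm <- poses[[i]]
  }

  qmat <- matrix(
    NA_real_, n, length(muscles) * 2,
    dimnames = list(NULL, paste0(
      "q_", rep(muscles, each = 2), "_", rep(c("W", "N"), length(muscles)), "_m"
    ))
  )
  cn_path <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    for (m in muscles) {
      qmat[i, paste0("q_", m, "_W_m")] <-
        muscle_length(anatomy, m, "working", poses[[i]])
      qmat[i, paste0("q_", m, "_N_m")] <-
        muscle_length(anatomy, m, "non_working", poses[[i]])
    }
    cn_path[i, ] <- pose_transform(poses[[i]], anatomy, anatomy$condyle$non_working)
  }
  rest <- c(
    stats::setNames(
      vapply(muscles, muscle_length, numeric(1), model = anatomy, side = "working"),
      paste0("q_", muscles, "_W_m")
    ),
    stats::setNames(
      vapply(muscles, muscle_length, numeric(1), model = anatomy, side = "non_working"),
      paste0("q_", muscles, "_N_m")
    )
  )

  pose_tbl <- tibble::tibble(
    t_s = t_grid,
    open_rad = vapply(poses, `[[`, numeric(1), "open"),
    yaw_rad = vapply(poses, `[[`, numeric(1), "yaw"),
    roll_rad = vapply(poses, `[[`, numeric(1), "roll")
  )
  dd_n <- sum(sqrt(rowSums(diff(cn_path)^2)))

  structure(
    list(
      food = path$food, path = path, anatomy = anatomy,
      t_s = t_grid, poses = poses, pose_tbl = pose_tbl,
      q = tibble::as_tibble(as.data.frame(qmat)),
      rest_lengths = rest,
      condyle_N_path = tibble::as_tibble(as.data.frame(cn_path)),
      dd = c(working = 0, non_working = dd_n),
      n_steps = n_steps
    ),
    class = "mandible_trajectory"
  )
}

#' @export
print.mandible_trajectory <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<mandible_trajectory> food %s, %d steps over %.3g s; ",
      "non-working condylar path %.2f mm\n"
    ),
    x$path$food_id, x$n_steps, max(x$t_s), 1000 * x$dd[["non_working"]]
  ))
  invisible(x)
}

side_code <- function(side) c(working = "W", non_working = "N")[[side]]

#' Muscle contraction from a trajectory
#'
#' Shortening of a muscle relative to its open-mouth start length,
#' `dq = q(0) - q(t)`, reported positive for shortening. `kind = "total"`
#' takes the closed-mouth end of the cycle, `"at_time"` an arbitrary grid
#' time `t_ref`, and `"at_max_force"` the time of that muscle's force
#' maximum (a force solution must be attached or supplied).
#'
#' @param trajectory A [run_ik()] result.
#' @param muscle Muscle name.
#' @param side `"working"` or `"non_working"`.
#' @param kind One of `"total"`, `"at_max_force"`, `"at_time"`.
#' @param t_ref Reference time for `kind = "at_time"`.
#' @param forces A [run_forces()] solution; required for
#'   `kind = "at_max_force"` unless already attached to the trajectory.
#' @return Contraction in metres (positive = shortening).
#' @export
contraction <- function(trajectory, muscle, side = SIDES,
                        kind = c("total", "at_max_force", "at_time"),
                        t_ref = NULL, forces = NULL) {
  side <- match.arg(side)
  kind <- match.arg(kind)
  col <- paste0("q_", muscle, "_", side_code(side), "_m")
  if (!col %in% names(trajectory$q)) {
    stop_chewsim("no length series for muscle ", deparse(muscle))
  }
  q <- trajectory$q[[col]]
  t_grid <- trajectory$t_s
  idx <- switch(kind,
    total = length(t_grid),
    at_time = {
      if (is.null(t_ref)) stop_chewsim("kind = 'at_time' needs t_ref")
      which.min(abs(t_grid - t_ref))
    },
    at_max_force = {
      forces <- forces %||% trajectory$forces
      if (is.null(forces)) {
        stop_chewsim(
          "kind = 'at_max_force' requires a force solution ",
          "(run run_forces() and pass it via 'forces')"
        )
      }
      fcol <- force_column(muscle, side)
      which.max(forces$series[[fcol]])
    }
  )
  q[1] - q[idx]
}
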