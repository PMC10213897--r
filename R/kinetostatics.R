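# Stage 2: quasi-static muscle-force equilibrium.
#
# At each time step the mandible is in equilibrium under the occlusal food
# force at IW, four active muscle forces (temporalis and V resultant per
# side) and one compressive contact normal per temporomandibular joint.
# With two point contacts the mandible retains 4 degrees of freedom, so the
# four muscle magnitudes follow from projecting all wrenches onto a basis
# of the 4-dimensional twist space compatible with the contacts (virtual
# work). The full 6-equation Newton-Euler system with the two contact
# normals as additional unknowns serves as an independent cross-check and
# supplies the joint reactions.
#
# Inertia and gravity are neglected: at the prescribed closing speed of
# 0.02 m/s mandibular inertia forces are orders of magnitude below the
# occlusal forces, so the "simple dynamics task" is solved kinetostatically.

# wrench of a unit force along direction u applied at point p (moment about
# the coordinate origin first, then force)
wrench <- function(p, u) c(cross3(p, u), u)

force_column <- function(muscle, side) {
  code <- c(
    masseter = "FM", medial_pterygoid = "FMP", temporalis = "FT",
    resultant_v = "FV", anterior_temporalis = "FAT",
    middle_temporalis = "FMT", posterior_temporalis = "FPT"
  )[[muscle]]
  paste0(code, "_", side_code(side), "_N")
}

# Geometry of one equilibrium step: transformed muscle lines, food wrench
# per unit force, contact points and normals.
step_geometry <- function(anatomy, pose) {
  lines <- list()
  for (m in c("temporalis", "resultant_v")) {
    for (s in c("working", "non_working")) {
      att <- anatomy$muscles[[m]][[s]]
      ins <- pose_transform(pose, anatomy, att$insertion)
      lines[[paste(m, s, sep = ".")]] <-
        list(p = ins, u = unit(att$origin - ins))
    }
  }
  W_mus <- vapply(
    lines[c(
      "temporalis.working", "temporalis.non_working",
      "resultant_v.working", "resultant_v.non_working"
    )],
    function(l) wrench(l$p, l$u), numeric(6)
  )
  p_iw <- pose_transform(pose, anatomy, anatomy$IW)
  w_food <- wrench(p_iw, -anatomy$occlusal_plane$normal)
  contacts <- list(
    working = list(
      p = anatomy$contact_point_W, n = anatomy$contact_normal_W
    ),
    non_working = list(
      p = pose_transform(pose, anatomy, anatomy$condyle$non_working),
      n = anatomy$guide_plane_N$normal
    )
  )
  list(W_mus = W_mus, w_food = w_food, contacts = contacts)
}

#' Solve the muscle-force equilibrium at one pose
#'
#' Solves the 4x4 virtual-work system for the four active muscle force
#' magnitudes (temporalis and V resultant, working and non-working side)
#' under a given occlusal force, and cross-checks against the 6x6
#' Newton-Euler formulation whose extra unknowns are the two condylar
#' contact normal reactions.
#'
#' @param anatomy An `anatomy_model`.
#' @param pose A converged pose from [solve_pose()].
#' @param food_force Occlusal force magnitude in newtons, applied at IW
#'   along the occlusal-plane normal opposing closure.
#' @param mode `"validation"` errors on a negative muscle force,
#'   `"exploratory"` warns and clamps to zero.
#' @return A list with `forces` (named: `FT_W`, `FT_N`, `FV_W`, `FV_N`, N),
#'   `reactions` (named: `R_W`, `R_N`, N, compressive positive),
#'   `crosscheck` (largest relative 4x4 vs 6x6 disagreement) and
#'   `residual` (net wrench norm of the 6x6 solution).
#' @export
solve_step <- function(anatomy, pose, food_force,
                       mode = c("validation", "exploratory")) {
  mode <- match.arg(mode)
  stopifnot(food_force >= 0)
  g <- step_geometry(anatomy, pose)

  # 4x4 virtual-work system on a twist basis compatible with the contacts
  C <- rbind(
    wrench(g$contacts$working$p, g$contacts$working$n),
    wrench(g$contacts$non_working$p, g$contacts$non_working$n)
  )
  Z <- svd(C, nu = 0, nv = 6)$v[, 3:6, drop = FALSE]
  A4 <- t(Z) %*% g$W_mus
  b4 <- -t(Z) %*% g$w_food * food_force
  f4 <- tryCatch(drop(solve(A4, b4)), error = function(e) {
    stop_chewsim(
      "singular 4x4 equilibrium at pose t = ", format(pose$t_s), " s"
    )
  })

  # 6x6 Newton-Euler cross-check; reactions on the mandible act opposite to
  # the outward (superior) plane normals, i.e. the joint surface pushes the
  # condyle back: compressive reactions are positive coefficients on -n.
  A6 <- cbind(
    g$W_mus,
    wrench(g$contacts$working$p, -g$contacts$working$n),
    wrench(g$contacts$non_working$p, -g$contacts$non_working$n)
  )
  x6 <- drop(solve(A6, -g$w_food * food_force))
  resid <- vnorm(A6 %*% x6 + g$w_food * food_force)

  scale <- max(abs(x6[1:4]), food_force, 1e-12)
  crosscheck <- max(abs(f4 - x6[1:4])) / scale

  forces <- stats::setNames(f4, c("FT_W", "FT_N", "FV_W", "FV_N"))
  if (any(forces < -1e-9 * max(scale, 1))) {
    msg <- paste0(
      "negative muscle force at t = ", format(pose$t_s), " s: ",
      paste(sprintf("%s=%.3g", names(forces), forces)[forces < 0], collapse = ", "),
      " (model infeasible at this pose)"
    )
    if (mode == "validation") stop_chewsim(msg)
    warning(msg, call. = FALSE)
    forces <- pmax(forces, 0)
  }
  list(
    forces = forces,
    reactions = stats::setNames(x6[5:6], c("R_W", "R_N")),
    crosscheck = crosscheck,
    residual = resid
  )
}

#' Run the force solve over a trajectory
#'
#' Evaluates the food curve along the closure, solves the per-step
#' equilibrium, and decomposes the V resultant into masseter and medial
#' pterygoid magnitudes by the planar split along the two anatomical
#' directions (a fixed linear map, hence a food-invariant FM / FMP ratio).
#'
#' @param anatomy An `anatomy_model`.
#' @param trajectory A [run_ik()] result for the same food.
#' @param food_curve A [food_curve()]; must refer to the trajectory's food.
#' @param mode See [solve_step()].
#' @return A `muscle_force_solution` with the time series tibble `series`
#'   (columns `t_s`, `F_N`, `FT_*`, `FV_*`, `FM_*`, `FMP_*`, `R_TMJ_*`),
#'   the split constants, and the worst-case equilibrium residual and 4x4
#'   vs 6x6 disagreement.
#' @export
run_forces <- function(anatomy, trajectory, food_curve,
                       mode = c("validation", "exploratory")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trajectory, "mandible_trajectory"))
  if (!identical(food_curve$food$id, trajectory$path$food_id)) {
    stop_chewsim(
      "food mismatch: trajectory is for '", trajectory$path$food_id,
      "', curve for '", food_curve$food$id, "'"
    )
  }
  t_grid <- trajectory$t_s
  dh <- trajectory$path$h + closing_position(trajectory$path, t_grid)$z_m
  F_food <- force_at(food_curve, dh)

  n <- length(t_grid)
  out <- matrix(0, n, 6, dimnames = list(NULL, c(
    "FT_W_N", "FT_N_N", "FV_W_N", "FV_N_N", "R_TMJ_W_N", "R_TMJ_N_N"
  )))
  crosscheck <- residual <- numeric(n)
  for (i in seq_len(n)) {
    st <- solve_step(anatomy, trajectory$poses[[i]], F_food[i], mode = mode)
    out[i, 1:4] <- st$forces
    out[i, 5:6] <- st$reactions
    crosscheck[i] <- st$crosscheck
    residual[i] <- st$residual
  }

  sc <- split_constants(anatomy)
  series <- tibble::tibble(
    t_s = t_grid, F_N = F_food,
    FT_W_N = out[, "FT_W_N"], FT_N_N = out[, "FT_N_N"],
    FV_W_N = out[, "FV_W_N"], FV_N_N = out[, "FV_N_N"],
    FM_W_N = sc[["masseter"]] * out[, "FV_W_N"],
    FM_N_N = sc[["masseter"]] * out[, "FV_N_N"],
    FMP_W_N = sc[["medial_pterygoid"]] * out[, "FV_W_N"],
    FMP_N_N = sc[["medial_pterygoid"]] * out[, "FV_N_N"],
    R_TMJ_W_N = out[, "R_TMJ_W_N"], R_TMJ_N_N = out[, "R_TMJ_N_N"]
  )
  structure(
    list(
      food_id = trajectory$path$food_id, curve = food_curve,
      series = series, split = sc,
      max_crosscheck = max(crosscheck), max_residual = max(residual)
    ),
    class = "muscle_force_solution"
  )
}

#' @export
print.muscle_force_solution <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<muscle_force_solution> food %s: peak occlusal force %.1f N, ",
      "peak FM_W %.1f N; worst 4x4 vs 6x6 disagreement %.2g\n"
    ),
    x$food_id, max(x$series$F_N), max(x$series$FM_W_N), x$max_crosscheck
  ))
  invisible(x)
}

#' Attach a force solution to a trajectory
#'
#' Needed for [contraction()] with `kind = "at_max_force"`.
#'
#' @param trajectory A [run_ik()] result.
#' @param solution The matching [run_forces()] solution.
#' @return The trajectory with the solution stored in `$forces`.
#' @export
attach_forces <- function(trajectory, solution) {
  stopifnot(
    inherits(trajectory, "mandible_trajectory"),
    inherits(solution, "muscle_force_solution"),
    identical(trajectory$path$food_id, solution$food_id)
  )
  trajectory$forces <- solution
  trajectory
}

#' Export a force solution as CSV
#'
#' @param solution A [run_forces()] solution (optionally with temporalis
#'   component columns from [augment_temporalis()]).
#' @param file Output file path.
#' @return The file path, invisibly.
#' @export
write_forces_csv <- function(solution, file) {
  write_csv_commented(
    as.data.frame(solution$series), file,
    comment = sprintf(
      "muscle force solution, food %s: times s, forces N", solution$food_id
    )
  )
  invisible(file)
}
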