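# Landmark anatomy of the skull-mandible system.
#
# The geometry is a landmark surrogate: each elevator muscle (and the
# resultant V line standing in for masseter + medial pterygoid in the force
# solve) is a straight line of action between an origin on the fixed skull
# and an insertion on the mobile mandible. Coordinates are metres in a frame
# with origin at the incisal end point IS, x anterior, y toward the left, z
# superior. The working side of the default build is the right side (y < 0);
# a left-working model is the exact mirror image through the sagittal plane.
#
# The free geometric parameters (attachment positions, line directions,
# guide-plane slope, chewing-path start offset) are pre-calibrated so that
# the full pipeline reproduces the bundled reference coefficients; see the
# methods vignette for the calibration targets and rationale.

MUSCLES <- c("masseter", "medial_pterygoid", "temporalis")
TEMPORALIS_PARTS <- c(
  "anterior_temporalis", "middle_temporalis", "posterior_temporalis"
)
SIDES <- c("working", "non_working")

PCSA_DEFAULT <- c(
  masseter = 6.80e-4, medial_pterygoid = 4.37e-4, temporalis = 8.23e-4
)

FIG_ANGLES_DEG <- c(
  alpha = 11, phi = 58, theta = 76, gamma = 42, beta = 22,
  delta = 20, lambda = 20
)

# PCSA-proportional fractions of the temporalis principal vector carried by
# its anterior, middle and posterior parts: sum-constrained least-squares
# fit of the reference component forces on the principal forces.
TEMPORALIS_FRACTIONS <- c(
  anterior = 0.479920, middle = 0.289993,
  posterior = 1 - 0.479920 - 0.289993
)

# Calibrated default values of the free geometric parameters (see
# data-raw-style calibration script under scripts/). Units: metres for
# coordinates, degrees for angles, dimensionless for path_rho.
DEFAULT_ANATOMY_PARAMS <- c(
  cond_x = -0.095, # condyle centre, anterior coordinate, m
  cond_y = 0.052208, # half intercondylar width, m
  cond_z = 0.035, # condyle centre above the occlusal plane, m
  iw_x = -0.055, # occlusal load point (first molar region), anterior, m
  iw_y = -0.002, # occlusal load point, lateral, m
  guide_psi = 25.012148, # guide-plane slope, forward-down, deg
  guide_mu = 14.281664, # guide-plane slope, medial-down, deg
  wcontact_kappa = 25.135045, # working contact normal sagittal tilt, deg
  wcontact_lat = 4.620518, # working contact normal lateral tilt, deg
  wcontact_dx = 0.001468, # working contact point offset from condyle, m
  wcontact_dy = 0.032,
  wcontact_dz = -0.030,
  m_ins_x = -0.058, m_ins_y = -0.028, m_ins_z = -0.017142, # masseter insertion
  m_tilt = 18.609846, m_lat = -17.444573, # masseter line tilt, deg
  p_ins_x = -0.067646, p_ins_y = -0.040506, p_ins_z = -0.014, # medial pterygoid
  p_tilt = 0.688231, p_lat = 1.090418, # medial pterygoid line tilt, deg
  t_ins_x = -0.004, t_ins_y = -0.030, t_ins_z = 0.030, # temporalis insertion
  t_tilt = -26.846696, t_lat = -25.120495, # temporalis line tilt, deg
  v_dx = 0.004970, v_dy = 0.016, v_dz = -0.016, # V anchor offset, m
  v_tilt = 24.341059, v_lat = 5.057959, # V-resultant line tilt, deg
  path_rho = 0.65 # chewing-path start offset fraction
)

MUSCLE_LENGTHS <- c(
  masseter = 0.065, medial_pterygoid = 0.062, temporalis = 0.070,
  resultant_v = 0.060
)

mirror_y <- function(p) c(p[1], -p[2], p[3])

# Unit line-of-action direction from in-sagittal tilt (deg, positive = pulls
# the insertion forward as well as up) and out-of-sagittal tilt (deg,
# positive = toward the midline for a right-side muscle).
line_direction <- function(tilt_deg, lat_deg, side_sign) {
  t <- deg2rad(tilt_deg)
  l <- deg2rad(lat_deg)
  c(sin(t) * cos(l), side_sign * sin(l), cos(t) * cos(l))
}

#' Build an anatomy model from a parameter vector
#'
#' Lower-level constructor used by [build_default_anatomy()] and by
#' [calibrate_anatomy()]. Parameters describe the working (right) side; the
#' non-working side is its mirror image through the sagittal plane.
#'
#' @param params Named numeric vector; defaults to the calibrated values.
#'   Unknown names are rejected.
#' @param working_side `"right"` or `"left"`.
#' @param pcsa Named PCSA vector in m^2 for the three principal muscles.
#' @return An object of class `anatomy_model`.
#' @export
anatomy_from_params <- function(params = DEFAULT_ANATOMY_PARAMS,
                                working_side = c("right", "left"),
                                pcsa = PCSA_DEFAULT) {
  working_side <- match.arg(working_side)
  full <- DEFAULT_ANATOMY_PARAMS
  if (!all(names(params) %in% names(full))) {
    stop_chewsim(
      "unknown anatomy parameter(s): ",
      paste(setdiff(names(params), names(full)), collapse = ", ")
    )
  }
  full[names(params)] <- params
  p <- as.list(full)
  stopifnot(all(pcsa > 0))

  # Working-side (right, y < 0) landmarks.
  cond_w <- vec3(p$cond_x, -p$cond_y, p$cond_z)
  cond_n <- mirror_y(cond_w)
  iw <- vec3(p$iw_x, p$iw_y, 0)

  ins <- list(
    masseter = vec3(p$m_ins_x, p$m_ins_y, p$m_ins_z),
    medial_pterygoid = vec3(p$p_ins_x, p$p_ins_y, p$p_ins_z),
    temporalis = vec3(p$t_ins_x, p$t_ins_y, p$t_ins_z),
    resultant_v = cond_w + c(p$v_dx, p$v_dy, p$v_dz)
  )
  dirs <- list(
    masseter = line_direction(p$m_tilt, p$m_lat, side_sign = 1),
    medial_pterygoid = line_direction(p$p_tilt, p$p_lat, side_sign = 1),
    temporalis = line_direction(p$t_tilt, p$t_lat, side_sign = 1),
    resultant_v = line_direction(p$v_tilt, p$v_lat, side_sign = 1)
  )
  muscles <- list()
  for (m in names(ins)) {
    org_w <- ins[[m]] + MUSCLE_LENGTHS[[m]] * dirs[[m]]
    muscles[[m]] <- list(
      working = list(insertion = ins[[m]], origin = org_w),
      non_working = list(
        insertion = mirror_y(ins[[m]]), origin = mirror_y(org_w)
      )
    )
  }

  # Temporalis part lines: insertions spread along the coronoid region, with
  # in-sagittal directions at the anterior/middle/posterior part angles
  # (theta, gamma, beta above the horizontal axis, backward pull).
  part_angles <- FIG_ANGLES_DEG[c("theta", "gamma", "beta")]
  part_offsets <- c(0.008, 0.000, -0.008)
  t_ins <- ins$temporalis
  for (i in seq_along(TEMPORALIS_PARTS)) {
    nm <- TEMPORALIS_PARTS[i]
    ip <- t_ins + c(part_offsets[i], 0, 0)
    dir <- unit(c(-cos(deg2rad(part_angles[i])), 0, sin(deg2rad(part_angles[i]))))
    org <- ip + MUSCLE_LENGTHS[["temporalis"]] * dir
    muscles[[nm]] <- list(
      working = list(insertion = ip, origin = org),
      non_working = list(insertion = mirror_y(ip), origin = mirror_y(org))
    )
  }

  # Non-working condylar guide plane: spanned by a forward-down slide
  # direction (slope psi) and a medial-down slide direction (slope mu);
  # normal oriented upward. The condyle slides downward, forward and
  # medially on this plane during opening.
  psi <- deg2rad(p$guide_psi)
  mu <- deg2rad(p$guide_mu)
  s1 <- c(cos(psi), 0, -sin(psi))
  s2 <- c(0, -cos(mu), -sin(mu)) # medial for the left (non-working) condyle
  n_guide <- unit(cross3(s1, s2))
  if (n_guide[3] < 0) n_guide <- -n_guide

  # Working-condyle contact normal (force model only: the working TMJ
  # transmits a single compressive normal force; kinematically the working
  # condyle is the fixed rotation centre).
  n_wcontact <- line_direction(p$wcontact_kappa, p$wcontact_lat, side_sign = 1)
  wcontact_point <- cond_w + c(p$wcontact_dx, p$wcontact_dy, p$wcontact_dz)

  model <- structure(
    list(
      working_side = working_side,
      params = full,
      condyle = list(working = cond_w, non_working = cond_n),
      IW = iw,
      IS = vec3(0, 0, 0),
      occlusal_plane = list(point = vec3(0, 0, 0), normal = vec3(0, 0, 1)),
      guide_plane_N = list(point = cond_n, normal = n_guide),
      contact_normal_W = n_wcontact,
      contact_point_W = wcontact_point,
      muscles = muscles,
      pcsa = pcsa,
      angles_deg = FIG_ANGLES_DEG,
      temporalis_fractions = TEMPORALIS_FRACTIONS,
      path_rho = full[["path_rho"]]
    ),
    class = "anatomy_model"
  )
  if (working_side == "left") model <- mirror_anatomy(model)
  model
}

# Mirror every landmark through the sagittal plane (y -> -y). Sides keep
# their working / non-working labels, so a left-working model has its
# working-side landmarks at y > 0.
mirror_anatomy <- function(model) {
  m <- model
  m$condyle <- lapply(model$condyle, mirror_y)
  m$IW <- mirror_y(model$IW)
  m$guide_plane_N <- list(
    point = mirror_y(model$guide_plane_N$point),
    normal = mirror_y(model$guide_plane_N$normal)
  )
  m$contact_normal_W <- mirror_y(model$contact_normal_W)
  m$contact_point_W <- mirror_y(model$contact_point_W)
  m$muscles <- lapply(model$muscles, function(sides) {
    lapply(sides, function(att) lapply(att, mirror_y))
  })
  m
}

#' Build the pre-calibrated default anatomy
#'
#' Returns the bundled landmark model of the skull-mandible system, with
#' muscle lines of action, PCSA constants, temporomandibular contact planes
#' and the temporalis part angles. The free geometric parameters carry their
#' calibrated values, chosen so that the full pipeline reproduces the
#' bundled reference force and contraction coefficients.
#'
#' @param working_side Side on which the food is chewed: `"right"`
#'   (default) or `"left"`. The left model is the mirror image of the right
#'   one.
#' @return An `anatomy_model`.
#' @examples
#' anatomy <- build_default_anatomy()
#' anatomy$pcsa
#' @export
build_default_anatomy <- function(working_side = c("right", "left")) {
  anatomy_from_params(working_side = match.arg(working_side))
}

#' @export
print.anatomy_model <- function(x, ...) {
  cat(sprintf(
    "<anatomy_model> working side: %s; intercondylar width %.3f m\n",
    x$working_side, 2 * abs(x$condyle$working[2])
  ))
  cat(
    " muscles:", paste(setdiff(names(x$muscles), TEMPORALIS_PARTS), collapse = ", "),
    "\n PCSA (m^2):", paste(sprintf("%s=%.2e", names(x$pcsa), x$pcsa), collapse = ", "),
    "\n"
  )
  invisible(x)
}

#' Muscle length at a mandibular pose
#'
#' Euclidean distance between the skull origin and the pose-transformed
#' mandibular insertion of a muscle line.
#'
#' @param model An `anatomy_model`.
#' @param muscle Muscle name (principal, `"resultant_v"`, or a temporalis
#'   part).
#' @param side `"working"` or `"non_working"`.
#' @param pose A pose from [solve_pose()], or `NULL` for the reference
#'   (closed) pose.
#' @return Length in metres.
#' @export
muscle_length <- function(model, muscle, side = SIDES, pose = NULL) {
  side <- match.arg(side)
  att <- model$muscles[[muscle]]
  if (is.null(att)) {
    stop_chewsim(
      "unknown muscle ", deparse(muscle), "; available: ",
      paste(names(model$muscles), collapse = ", ")
    )
  }
  ins <- att[[side]]$insertion
  if (!is.null(pose)) ins <- pose_transform(pose, model, ins)
  vnorm(att[[side]]$origin - ins)
}

# Constants of the planar decomposition of the V resultant into masseter and
# medial pterygoid magnitudes: least-squares coefficients of the V direction
# on the two anatomical directions at the reference (closed) pose. Constant
# across the cycle by construction, hence a food-invariant FM / FMP ratio.
split_constants <- function(model) {
  u_m <- with(model$muscles$masseter$working, unit(origin - insertion))
  u_p <- with(model$muscles$medial_pterygoid$working, unit(origin - insertion))
  u_v <- with(model$muscles$resultant_v$working, unit(origin - insertion))
  B <- cbind(u_m, u_p)
  coef <- drop(solve(crossprod(B), crossprod(B, u_v)))
  stats::setNames(unname(coef), c("masseter", "medial_pterygoid"))
}
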