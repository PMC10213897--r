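# Inverse kinematics: pose solving, trajectories, contractions.

test_that("solved poses satisfy all constraints to solver precision", {
  an <- default_anatomy()
  path <- make_path("c")
  gp <- an$guide_plane_N
  for (t in seq(0, path$t_chew, length.out = 21)) {
    pose <- solve_pose(an, path, t)
    # incisal point on the prescribed frontal-plane position (round trip)
    target <- closing_position(path, t)
    is_t <- pose_transform(pose, an, an$IS)
    expect_lt(abs(is_t[2] - target$y_m), 1e-9)
    expect_lt(abs(is_t[3] - target$z_m), 1e-9)
    # working condyle fixed centre
    cw <- pose_transform(pose, an, an$condyle$working)
    expect_lt(sqrt(sum((cw - an$condyle$working)^2)), 1e-9)
    # non-working condyle on the guide plane
    cn <- pose_transform(pose, an, an$condyle$non_working)
    expect_lt(abs(sum(gp$normal * (cn - gp$point))), 1e-9)
  }
  # closure endpoint is the identity pose
  pose_end <- solve_pose(an, path, path$t_chew)
  expect_lt(max(abs(c(pose_end$open, pose_end$yaw, pose_end$roll))), 1e-9)
})

test_that("the non-working condyle slides downward, forward and medially", {
  an <- default_anatomy()
  traj <- one_food_sim("s")$foods$s$trajectory
  p <- traj$condyle_N_path
  open_pos <- unlist(p[1, ]) # most open
  closed_pos <- unlist(p[nrow(p), ]) # occlusion
  # during opening (closed -> open) the condyle moves forward (+x),
  # downward (-z) and medially (toward the midline; left condyle y > 0)
  expect_gt(open_pos["x"], closed_pos["x"])
  expect_lt(open_pos["z"], closed_pos["z"])
  expect_lt(abs(open_pos["y"]), abs(closed_pos["y"]))
})

test_that("condylar path lengths: fixed working centre, mobile non-working", {
  traj <- one_food_sim("s")$foods$s$trajectory
  expect_equal(unname(traj$dd["working"]), 0)
  expect_gt(unname(traj$dd["non_working"]), 0)
})

test_that("muscle length series are continuous and shorten during closing", {
  sim <- full_sim()
  for (f in names(sim$foods)) {
    q <- sim$foods[[f]]$trajectory$q
    for (col in names(q)) {
      # step-to-step continuity of the warm-started solution
      expect_lt(max(abs(diff(q[[col]]))), 2.5e-4)
    }
    for (m in c("masseter", "medial_pterygoid", "temporalis")) {
      for (sd in c("W", "N")) {
        series <- q[[paste0("q_", m, "_", sd, "_m")]]
        # elevators shorten over the cycle: the start is within a fraction
        # of a millimetre of the longest state, occlusion of the shortest,
        # and transient per-step lengthening along the curved arc is tiny
        expect_lt(max(series) - series[1], 3e-4)
        expect_lt(series[length(series)] - min(series), 3e-4)
        expect_gt(series[1] - series[length(series)], 1e-3)
        expect_lt(max(diff(series)), 1e-4)
      }
    }
  }
})

test_that("contraction kinds follow their definitions", {
  sim <- one_food_sim("d")
  traj <- sim$foods$d$trajectory
  # zero at the start of the cycle
  expect_equal(
    contraction(traj, "masseter", "working", "at_time", t_ref = 0), 0
  )
  # at_time with t_ref = t_chew equals total
  expect_equal(
    contraction(traj, "masseter", "working", "at_time",
      t_ref = max(traj$t_s)
    ),
    contraction(traj, "masseter", "working", "total")
  )
  # at_max_force needs an attached force solution
  bare <- traj
  bare$forces <- NULL
  expect_error(
    contraction(bare, "masseter", "working", "at_max_force"),
    "force solution"
  )
  dq_h <- contraction(traj, "masseter", "working", "at_max_force")
  expect_gt(dq_h, 0)
  expect_lt(dq_h, contraction(traj, "masseter", "working", "total"))
})

test_that("simulated chocolate masseter contraction matches the reference", {
  sim <- full_sim()
  dq <- contraction(sim$foods$d$trajectory, "masseter", "working", "total")
  expect_equal(dq, 4.2e-3, tolerance = 0.05)
})

test_that("n_steps below the supported minimum is rejected", {
  an <- default_anatomy()
  expect_error(run_ik(an, make_path("d"), n_steps = 10), "at least 50")
})
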