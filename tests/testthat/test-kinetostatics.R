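# Quasi-static equilibrium solve and its Newton-Euler cross-check.

test_that("zero load gives zero muscle force; scaling is linear", {
  an <- default_anatomy()
  pose <- solve_pose(an, make_path("d"), 0.2)
  st0 <- solve_step(an, pose, 0)
  expect_equal(unname(st0$forces), rep(0, 4))
  st1 <- solve_step(an, pose, 50)
  st2 <- solve_step(an, pose, 100)
  expect_equal(unname(st2$forces), unname(2 * st1$forces), tolerance = 1e-12)
  expect_equal(unname(st2$reactions), unname(2 * st1$reactions),
    tolerance = 1e-12
  )
})

test_that("virtual-work and Newton-Euler solutions agree at every step", {
  sim <- full_sim()
  for (f in names(sim$foods)) {
    expect_lt(sim$foods[[f]]$solution$max_crosscheck, 1e-3)
    expect_lt(sim$foods[[f]]$solution$max_residual, 1e-6)
  }
})

test_that("muscle forces and joint reactions stay non-negative", {
  sim <- full_sim()
  for (f in names(sim$foods)) {
    s <- sim$foods[[f]]$solution$series
    for (col in c(
      "FT_W_N", "FT_N_N", "FV_W_N", "FV_N_N", "FM_W_N", "FM_N_N",
      "FMP_W_N", "FMP_N_N", "R_TMJ_W_N", "R_TMJ_N_N"
    )) {
      expect_true(all(s[[col]] >= -1e-9), label = paste(f, col))
    }
  }
})

test_that("muscle force peaks are synchronous with the food force peak", {
  sim <- full_sim()
  for (f in names(sim$foods)) {
    s <- sim$foods[[f]]$solution$series
    i_food <- which.max(s$F_N)
    for (col in c("FM_W_N", "FMP_W_N", "FM_N_N", "FT_W_N")) {
      if (f %in% c("d", "a", "c")) {
        # brittle foods: sharp force peak, strict synchrony
        expect_lte(abs(which.max(s[[col]]) - i_food), 1, label = paste(f, col))
      } else if (col == "FT_W_N") {
        # the temporalis ratio does not grow with closure: synchronous
        expect_lte(abs(which.max(s[[col]]) - i_food), 2, label = paste(f, col))
      } else {
        # ductile foods keep a force plateau to occlusion and the V-line
        # ratio grows with closure, so the masseter / pterygoid maximum
        # sits at the end of the cycle rather than at the food peak
        expect_gte(which.max(s[[col]]), nrow(s) - 2, label = paste(f, col))
      }
    }
  }
})

test_that("FM / FMP ratio is the reference constant for every food", {
  sim <- full_sim()
  for (f in names(sim$foods)) {
    s <- sim$foods[[f]]$solution$series
    i <- which.max(s$F_N)
    expect_equal(s$FM_W_N[i] / s$FMP_W_N[i], 1.215 / 1.089, tolerance = 0.01)
    expect_equal(s$FM_N_N[i] / s$FMP_N_N[i], 1.215 / 1.089, tolerance = 0.01)
  }
})

test_that("simulated peak forces match the reference working-side values", {
  sim <- full_sim()
  # dark chocolate: peak working masseter force over peak occlusal force
  sd <- sim$foods$d$solution$series
  expect_equal(max(sd$FM_W_N) / max(sd$F_N), 1.215, tolerance = 0.01)
  # carrot: absolute peak working masseter force
  expect_equal(max(sim$foods$c$solution$series$FM_W_N), 274.3,
    tolerance = 0.02
  )
})

test_that("reversed load direction is flagged as infeasible", {
  an <- default_anatomy()
  an$occlusal_plane$normal <- -an$occlusal_plane$normal # food pulls the jaw shut
  pose <- solve_pose(build_default_anatomy(), make_path("d"), 0.2)
  expect_error(solve_step(an, pose, 100), "negative muscle force")
  expect_warning(
    st <- solve_step(an, pose, 100, mode = "exploratory"),
    "negative muscle force"
  )
  expect_true(all(st$forces >= 0))
})

test_that("food mismatch between curve and trajectory is caught", {
  sim <- one_food_sim("d")
  expect_error(
    run_forces(default_anatomy(), sim$foods$d$trajectory, food_curve("s")),
    "food mismatch"
  )
})
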