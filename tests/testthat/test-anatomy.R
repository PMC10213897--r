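# Landmark anatomy, mirroring and the V-resultant split.

test_that("default anatomy carries the reference constants", {
  an <- default_anatomy()
  expect_equal(unname(an$pcsa["masseter"]), 6.80e-4)
  expect_equal(unname(an$pcsa["medial_pterygoid"]), 4.37e-4)
  expect_equal(unname(an$pcsa["temporalis"]), 8.23e-4)
  expect_equal(unname(an$angles_deg), c(11, 58, 76, 42, 22, 20, 20))
  # occlusal load point on the working (right) side
  expect_lt(an$IW[2], 0)
  expect_equal(unname(an$IS), c(0, 0, 0))
  expect_equal(sqrt(sum(an$guide_plane_N$normal^2)), 1)
})

test_that("left-working model is the exact mirror image", {
  r <- build_default_anatomy("right")
  l <- build_default_anatomy("left")
  mir <- function(p) c(p[1], -p[2], p[3])
  expect_equal(l$condyle$working, mir(r$condyle$working))
  expect_equal(l$IW, mir(r$IW))
  expect_equal(l$guide_plane_N$normal, mir(r$guide_plane_N$normal))
  for (m in names(r$muscles)) {
    for (s in c("working", "non_working")) {
      expect_equal(
        l$muscles[[m]][[s]]$insertion, mir(r$muscles[[m]][[s]]$insertion)
      )
      expect_equal(
        l$muscles[[m]][[s]]$origin, mir(r$muscles[[m]][[s]]$origin)
      )
    }
  }
})

test_that("muscle lengths behave geometrically", {
  an <- default_anatomy()
  # identity pose = rest length
  id_pose <- solve_pose(an, make_path("d"), food_specimen("d")$t_chew_s)
  for (m in c("masseter", "temporalis", "resultant_v")) {
    expect_equal(
      muscle_length(an, m, "working", id_pose),
      muscle_length(an, m, "working"),
      tolerance = 1e-9
    )
  }
  # pure closing rotation: temporalis strictly shortens
  lens <- vapply(seq(0.25, 0, length.out = 20), function(open) {
    pose <- structure(
      list(open = open, yaw = 0, roll = 0, t_s = NA),
      class = "mandible_pose"
    )
    muscle_length(an, "temporalis", "working", pose)
  }, numeric(1))
  expect_true(all(diff(lens) < 0))
  # mirrored model + mirrored (identical) pure-opening pose: same lengths
  l <- build_default_anatomy("left")
  pose <- structure(
    list(open = 0.2, yaw = 0, roll = 0, t_s = NA),
    class = "mandible_pose"
  )
  expect_equal(
    muscle_length(an, "masseter", "working", pose),
    muscle_length(l, "masseter", "working", pose),
    tolerance = 1e-12
  )
  expect_error(muscle_length(an, "platysma", "working"), "unknown muscle")
})

test_that("V split constants give the food-invariant FM/FMP ratio", {
  an <- default_anatomy()
  sc <- split_constants(an)
  expect_equal(
    unname(sc["masseter"] / sc["medial_pterygoid"]),
    1.215 / 1.089,
    tolerance = 1e-6
  )
})

test_that("all muscle lines elevate at every pose of a run", {
  # elevating line of action <=> the muscle lengthens as the mouth opens
  # (so its tension closes the jaw) at every pose reached during a cycle
  an <- default_anatomy()
  path <- make_path("s")
  eps <- 1e-5
  for (t in seq(0, path$t_chew, length.out = 7)) {
    pose <- solve_pose(an, path, t)
    pose_up <- pose
    pose_up$open <- pose$open + eps
    for (m in c("masseter", "medial_pterygoid", "temporalis", "resultant_v")) {
      for (s in c("working", "non_working")) {
        dq <- muscle_length(an, m, s, pose_up) - muscle_length(an, m, s, pose)
        expect_gt(dq, 0)
      }
    }
  }
})

test_that("mirror symmetry carries through the whole pipeline", {
  r <- simulate_chewing("d", working_side = "right", n_steps = 60)
  l <- simulate_chewing("d", working_side = "left", n_steps = 60)
  expect_equal(
    as.data.frame(r$foods$d$trajectory$q),
    as.data.frame(l$foods$d$trajectory$q),
    tolerance = 1e-9
  )
  expect_equal(
    as.data.frame(r$foods$d$solution$series),
    as.data.frame(l$foods$d$solution$series),
    tolerance = 1e-9
  )
})
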