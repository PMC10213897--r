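# Food catalogue and parametric force-deformation curves.

test_that("catalogue returns the reference specimen dimensions", {
  cat <- food_catalog()
  expect_setequal(cat$id, c("d", "b", "a", "c", "s"))

  c_row <- food_specimen("c")
  expect_equal(c_row$h_m, 19.6e-3)
  expect_equal(c_row$t_chew_s, 1.08)

  d_row <- food_specimen("d")
  expect_equal(d_row$h_m, 9.1e-3)
  expect_equal(d_row$t_chew_s, 0.51)

  expect_error(food_specimen("x"), "valid ids.*d, b, a, c, s")
})

test_that("default peak force inverts the working-masseter proportionality", {
  # oracle: reference maximum working masseter force / R_F = F_peak; the
  # medial pterygoid row must give the same peak force to within 0.2 %
  forces <- reference_table("max_forces_contractions")
  ratios <- reference_table("force_ratios")
  for (f in c("d", "c", "a")) {
    fm <- forces[forces$food == f & forces$side == "working" &
      forces$muscle == "masseter", ]$F_H_N
    fmp <- forces[forces$food == f & forces$side == "working" &
      forces$muscle == "medial_pterygoid", ]$F_H_N
    r_m <- ratios$R_F[ratios$side == "working" & ratios$muscle == "masseter"]
    r_p <- ratios$R_F[ratios$side == "working" &
      ratios$muscle == "medial_pterygoid"]
    expect_equal(default_peak_force(f), fm / r_m)
    # the two inversion routes agree to 0.2 % for chocolate and to the
    # rounding slack of the printed forces for the rest
    expect_equal(fm / r_m, fmp / r_p,
      tolerance = if (f == "d") 0.002 else 0.01
    )
  }
  expect_equal(default_peak_force("d"), 233.2 / 1.215)
  expect_equal(default_peak_force("c"), 274.3 / 1.215)
  expect_equal(default_peak_force("a"), 112.2 / 1.215)
})

test_that("curves satisfy their shape invariants for every food", {
  for (f in c("d", "b", "a", "c", "s")) {
    crv <- food_curve(f)
    h <- crv$food$h_m
    dh <- seq(0, h, length.out = 2001)
    F <- force_at(crv, dh)
    expect_equal(F[1], 0)
    expect_true(all(F >= 0))
    # peak position and value
    expect_equal(max(F), crv$F_peak, tolerance = 1e-4)
    expect_lt(abs(dh[which.max(F)] - crv$p_peak * h), h / 2000 + 1e-12)
    expect_equal(force_at(crv, crv$p_peak * h), crv$F_peak)
    # terminal force bounded by the peak
    expect_lte(force_at(crv, h), crv$F_peak)
    # texture classes
    post <- dh > crv$p_peak * h
    if (crv$shape == "brittle") {
      # drops below half peak within the post-peak envelope width
      half_at <- dh[post][which(F[post] < 0.5 * crv$F_peak)[1]]
      expect_lt(
        half_at - crv$p_peak * h,
        0.5 * (1 - crv$p_peak) * h
      )
    } else {
      keep <- dh / h <= 0.9
      expect_true(all(F[post & keep] >= 0.5 * crv$F_peak))
    }
  }
  expect_true(all(vapply(c("d", "c", "a"), function(f) {
    food_curve(f)$shape == "brittle"
  }, logical(1))))
  expect_true(all(vapply(c("b", "s"), function(f) {
    food_curve(f)$shape == "ductile"
  }, logical(1))))
})

test_that("force_at rejects out-of-range deformations", {
  crv <- food_curve("d")
  expect_error(force_at(crv, -0.001), "out of range")
  expect_error(force_at(crv, crv$food$h_m + 0.001), "out of range")
})

test_that("default peak fraction equals the reference contraction ratio", {
  forces <- reference_table("max_forces_contractions")
  for (f in c("d", "b", "a", "c", "s")) {
    row <- forces[forces$food == f & forces$side == "working" &
      forces$muscle == "masseter", ]
    expect_equal(default_peak_fraction(f), row$dq_H_m / row$dq_C_m)
  }
  expect_equal(default_peak_fraction("d"), 0.5, tolerance = 0.01)
})

test_that("time profiles compose the curve with a closure function", {
  crv <- food_curve("d")
  h <- crv$food$h_m
  t_chew <- crv$food$t_chew_s

  tp <- time_profiles(crv, n_steps = 100) # uniform closure default
  expect_equal(tp$F_N[1], 0)
  expect_equal(tp$dh_m[1], 0)
  expect_equal(tp$dh_m[nrow(tp)], h)

  # peak force occurs where the closure crosses p_peak * h (dense-scan oracle)
  i_peak <- which.max(tp$F_N)
  expect_lt(abs(tp$dh_m[i_peak] - crv$p_peak * h), h / 100 + 1e-12)

  # chew-path closure: same property through the composed pipeline
  path <- make_path("d")
  tp2 <- time_profiles(crv, closure = closure_function(path), n_steps = 200)
  i2 <- which.max(tp2$F_N)
  expect_lt(abs(tp2$dh_m[i2] - crv$p_peak * h), 2 * h / 200)

  expect_error(
    time_profiles(crv, closure = function(t) h * (1 - t / t_chew)),
    "non-decreasing|map 0"
  )
})

test_that("curve noise is seeded and off by default", {
  crv <- food_curve("d")
  a <- time_profiles(crv, n_steps = 50)
  b <- time_profiles(crv, n_steps = 50)
  expect_identical(a, b)
  n1 <- time_profiles(crv, n_steps = 50, noise_sd = 0.05, seed = 42)
  n2 <- time_profiles(crv, n_steps = 50, noise_sd = 0.05, seed = 42)
  expect_identical(n1, n2)
  expect_false(identical(a$F_N, n1$F_N))
})
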