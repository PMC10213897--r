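# Metrics: maxima, stiffness, intrinsic strength, proportionality,
# side-asymmetry summaries and the non-linear stiffness fit.

test_that("intrinsic strength is an exact arithmetic inversion", {
  sim <- one_food_sim("d")
  m <- sim$foods$d$metrics
  an <- default_anatomy()
  for (mu in c("masseter", "medial_pterygoid", "temporalis")) {
    row <- m[m$muscle == mu & m$side == "working", ]
    expect_equal(row$k_N_per_m2 * an$pcsa[[mu]], row$F_H_N, tolerance = 1e-12)
  }
  # temporalis parts inherit the principal's intrinsic strength
  kt <- m$k_N_per_m2[m$muscle == "temporalis" & m$side == "working"]
  kat <- m$k_N_per_m2[m$muscle == "anterior_temporalis" & m$side == "working"]
  expect_equal(kat, kt, tolerance = 1e-12)
})

test_that("summary rows are internally consistent", {
  sim <- one_food_sim("d")
  m <- sim$foods$d$metrics
  s <- sim$foods$d$solution$series
  row <- m[m$muscle == "masseter" & m$side == "working", ]
  expect_equal(row$F_H_N, max(s$FM_W_N))
  expect_equal(row$K_N_per_m, row$F_H_N / row$dq_H_m)
  expect_true(all(m$defined))
  expect_true(all(m$K_N_per_m > 0))
})

test_that("an all-zero force series yields flagged rows without K or k", {
  sim <- one_food_sim("d")
  sol <- sim$foods$d$solution
  sol$series[, setdiff(names(sol$series), "t_s")] <- 0
  m <- summarize_metrics(sol, sim$foods$d$trajectory)
  expect_true(all(!m$defined))
  expect_true(all(is.na(m$K_N_per_m)))
  expect_true(all(is.na(m$k_N_per_m2)))
})

test_that("reference contraction proportionality reproduces the constants", {
  prop <- proportionality(reference_metrics_table())
  rq <- function(mu, sd) prop$R_q[prop$muscle == mu & prop$side == sd]
  expect_equal(rq("masseter", "working"), 0.46, tolerance = 0.01)
  expect_equal(rq("temporalis", "working"), 0.74, tolerance = 0.01)
  expect_equal(rq("masseter", "non_working"), 0.55, tolerance = 0.01)
  # bad food table is rejected
  expect_error(
    proportionality(
      reference_metrics_table(),
      tibble::tibble(food = "d", F_max_N = 0, h_m = 0.0091)
    ),
    "positive"
  )
})

test_that("single-food proportionality reproduces the inversion input", {
  # circular identity: F_max obtained by inverting F_H = R_F F_max makes
  # the recomputed R_F equal the inversion constant exactly
  ref <- reference_metrics_table()
  one <- ref[ref$food == "d", ]
  prop <- proportionality(
    one,
    tibble::tibble(food = "d", F_max_N = 233.2 / 1.215, h_m = 0.0091)
  )
  expect_equal(
    prop$R_F[prop$muscle == "masseter" & prop$side == "working"], 1.215
  )
})

test_that("side asymmetry on the reference tables gives the headline values", {
  asym <- side_asymmetry(reference_metrics_table())
  val <- function(m) asym$value[asym$metric == m]
  expect_equal(val("force_deficit_pct"), 14, tolerance = 0.05)
  expect_equal(val("contraction_deficit_pct"), 17, tolerance = 0.05)
  expect_equal(val("stiffness_deficit_pct"), 29, tolerance = 0.05)
  expect_equal(val("stiffness_group_ratio"), 2.7, tolerance = 0.05)
  expect_equal(val("strength_mp_deficit_pct"), 28, tolerance = 0.05)
  expect_equal(val("force_mp_deficit_pct"), 10, tolerance = 0.06)
})

test_that("identical sides give zero deficits; missing cells error", {
  ref <- reference_metrics_table()
  sym <- ref
  w <- sym[sym$side == "working", ]
  n <- w
  n$side <- "non_working"
  sym <- rbind(w, n)
  asym <- side_asymmetry(sym)
  expect_equal(
    asym$value[asym$metric %in% c(
      "force_deficit_pct", "contraction_deficit_pct", "stiffness_deficit_pct"
    )],
    rep(0, 3),
    tolerance = 1e-12
  )
  expect_error(
    side_asymmetry(ref[ref$food != "s", ]),
    "missing cells"
  )
})

test_that("stiffness fit recovers closed-form stiffness laws", {
  dq <- seq(0, 5e-3, length.out = 60)
  # linear: F = c dq -> K = c everywhere
  fit_lin <- stiffness_fit(dq, 2.4e4 * dq)
  at <- seq(0.5e-3, 4.5e-3, length.out = 11)
  expect_equal(fit_lin$K(at), rep(2.4e4, 11), tolerance = 1e-6)
  # quadratic: F = a dq^2 -> K = 2 a dq
  a <- 5e6
  fit_q <- stiffness_fit(dq, a * dq^2)
  expect_equal(fit_q$K(at), 2 * a * at, tolerance = 0.01)
  # plateau: K -> 0 on the plateau
  Fp <- pmin(3e4 * dq, 60)
  fit_p <- stiffness_fit(dq, Fp)
  expect_lt(abs(fit_p$K(4.8e-3)), 1e-3 * 3e4)
  # guard rails
  expect_error(stiffness_fit(dq[1:10], dq[1:10]), "at least 20")
  expect_error(stiffness_fit(dq, sin(dq * 4000) * 10 + dq), "non-monotone")
})

test_that("simulated stiffness function reports the tangent-secant gap", {
  sim <- one_food_sim("d")
  sf <- stiffness_function(
    sim$foods$d$solution, sim$foods$d$trajectory, "masseter", "working"
  )
  expect_gt(sf$K_secant, 0)
  expect_true(is.finite(sf$K_tangent_at_H))
  expect_gte(sf$secant_gap, 0)
  # evaluating inside the fitted range reproduces the force samples
  mid <- mean(sf$dq_range)
  expect_gt(sf$value(mid), 0)
})
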