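# PCSA-proportional decomposition of the temporalis principal vector.

test_that("fractions sum to one and components conserve the input", {
  fr <- chewsim:::TEMPORALIS_FRACTIONS
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  for (ft in c(0, 0.3, 29.3, 46.1, 250)) {
    s <- split_temporalis(ft)
    expect_equal(s$FAT_N + s$FMT_N + s$FPT_N, ft, tolerance = 1e-12)
    expect_true(s$FAT_N >= s$FMT_N && s$FMT_N >= s$FPT_N)
  }
  expect_error(split_temporalis(-1), "non-negative")
})

test_that("the reference decomposition is reproduced cell by cell", {
  # chocolate working side: 46.1 N -> (22.1, 13.4, 10.6) at one decimal
  s <- split_temporalis(46.1)
  expect_equal(round(s$FAT_N, 1), 22.1)
  expect_equal(round(s$FMT_N, 1), 13.4)
  expect_equal(round(s$FPT_N, 1), 10.6)
  # chocolate-bar working side: the reference prints (14.1, 8.5, 6.7);
  # the shared fractions land within one rounding unit of each cell
  s2 <- split_temporalis(29.3)
  expect_lt(abs(s2$FAT_N - 14.1), 0.1)
  expect_lt(abs(s2$FMT_N - 8.5), 0.06)
  expect_lt(abs(s2$FPT_N - 6.7), 0.06)

  # across all 30 reference cells, >= 27 match after 1-decimal rounding
  ref <- reference_table("max_forces_contractions")
  part_of <- c(
    anterior_temporalis = "FAT_N", middle_temporalis = "FMT_N",
    posterior_temporalis = "FPT_N"
  )
  rnd1 <- function(x) floor(x * 10 + 0.5) / 10 # print-style rounding
  matches <- 0
  for (f in unique(ref$food)) {
    for (sd in unique(ref$side)) {
      ft <- ref$F_H_N[ref$food == f & ref$side == sd &
        ref$muscle == "temporalis"]
      sp <- split_temporalis(ft)
      for (p in names(part_of)) {
        printed <- ref$F_H_N[ref$food == f & ref$side == sd & ref$muscle == p]
        if (rnd1(sp[[part_of[[p]]]]) == printed) matches <- matches + 1
      }
    }
  }
  expect_gte(matches, 27)
})

test_that("fractions agree with a least-squares fit of the reference cells", {
  # independent oracle: regress each part's printed force on the principal
  ref <- reference_table("max_forces_contractions")
  ft <- ref[ref$muscle == "temporalis", c("food", "side", "F_H_N")]
  fr <- chewsim:::TEMPORALIS_FRACTIONS
  parts <- c(
    anterior = "anterior_temporalis", middle = "middle_temporalis",
    posterior = "posterior_temporalis"
  )
  for (p in names(parts)) {
    part <- ref[ref$muscle == parts[[p]], c("food", "side", "F_H_N")]
    j <- merge(ft, part, by = c("food", "side"))
    fit <- stats::lm(F_H_N.y ~ 0 + F_H_N.x, data = j)
    expect_equal(unname(stats::coef(fit)), unname(fr[[p]]), tolerance = 5e-3)
  }
})

test_that("augment appends component columns consistent with the split", {
  sol <- one_food_sim("d")$foods$d$solution
  s <- sol$series
  expect_true(all(c("FAT_W_N", "FMT_N_N", "FPT_W_N") %in% names(s)))
  expect_equal(s$FAT_W_N + s$FMT_W_N + s$FPT_W_N, s$FT_W_N, tolerance = 1e-12)
})
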