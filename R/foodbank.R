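# Food specimens and parametric force-deformation curves.
#
# The load on the masticatory model is the food characteristic F = f(dh):
# resistance force versus reduction of specimen height during compression
# between the dental arches. The measured characteristics are not available
# in tabulated form, so the package generates parametric stand-ins: a
# power-law rise to a peak force at a stated fraction of full closure,
# followed by a brittle drop or a ductile plateau.

FOOD_IDS <- c("d", "b", "a", "c", "s")

#' Catalogue of the five food specimens
#'
#' Mean specimen height, width, length and chewing time for the five foods:
#' dark chocolate (`d`), chocolate bar (`b`), apple (`a`), carrot (`c`) and
#' sausage (`s`). Values are the bundled reference means; widths of the
#' cylindrical specimens (carrot, sausage) are not part of the reference set
#' and are `NA`.
#'
#' @return A tibble with columns `id`, `label`, `h_m`, `w_m`, `l_m`,
#'   `t_chew_s`.
#' @examples
#' food_catalog()
#' @export
food_catalog <- function() {
  reference_table("foods")
}

#' Look up one food specimen
#'
#' @param food_id One of `"d"`, `"b"`, `"a"`, `"c"`, `"s"`.
#' @return A one-row tibble with the specimen dimensions and chewing time.
#' @examples
#' food_specimen("c")
#' @export
food_specimen <- function(food_id) {
  if (length(food_id) != 1 || !food_id %in% FOOD_IDS) {
    stop_chewsim(
      "unknown food id ", deparse(food_id),
      "; valid ids are: ", paste(FOOD_IDS, collapse = ", ")
    )
  }
  cat <- food_catalog()
  cat[cat$id == food_id, , drop = FALSE]
}

#' Default peak resistance force of a food
#'
#' The measured curves never state their peak force directly; the default is
#' recovered by inverting the linear force-proportionality relation
#' `F_H = R_F * F_max` for the working-side masseter: the bundled reference
#' maximum masseter force divided by the reference coefficient `R_F = 1.215`.
#' This is the calibration used to build the default curves; the same
#' inversion through the medial pterygoid row agrees to within 0.2 %.
#'
#' @param food_id Food identifier.
#' @return Peak force in newtons.
#' @examples
#' default_peak_force("d") # 233.2 / 1.215
#' @export
default_peak_force <- function(food_id) {
  food_specimen(food_id) # validates the id
  forces <- reference_table("max_forces_contractions")
  row <- forces[forces$food == food_id & forces$side == "working" &
    forces$muscle == "masseter", ]
  ratios <- reference_table("force_ratios")
  r_fw <- ratios[ratios$side == "working" & ratios$muscle == "masseter", ]$R_F
  row$F_H_N / r_fw
}

#' Default peak-force position of a food
#'
#' Fraction of total closure at which the resistance force peaks. Because
#' muscle contraction is monotone in closure, the ratio of the reference
#' working-masseter contraction at maximum force to its total contraction
#' transfers to the closure fraction of the force peak.
#'
#' @param food_id Food identifier.
#' @return Dimensionless fraction in (0, 1).
#' @export
default_peak_fraction <- function(food_id) {
  food_specimen(food_id)
  forces <- reference_table("max_forces_contractions")
  row <- forces[forces$food == food_id & forces$side == "working" &
    forces$muscle == "masseter", ]
  row$dq_H_m / row$dq_C_m
}

default_shape <- function(food_id) {
  # sharp post-peak drop for the products that fracture (chocolate, carrot,
  # apple); post-peak plateau for the ductile ones (chocolate bar, sausage)
  if (food_id %in% c("d", "c", "a")) "brittle" else "ductile"
}

#' Parametric force-deformation curve of a food
#'
#' Builds the parametric characteristic `F = f(dh)` of a food specimen:
#' a power-law rise `(dh / (p_peak h))^rise_exponent` up to the peak at
#' `dh = p_peak * h`, followed by a Gaussian post-peak envelope. Brittle
#' curves drop below half the peak force within the configured post-peak
#' width; ductile curves decay onto a plateau and never fall below it.
#'
#' @param food_id Food identifier, or a one-row tibble from
#'   [food_specimen()].
#' @param F_peak Peak resistance force, N. Defaults to
#'   [default_peak_force()].
#' @param p_peak Fraction of total closure at which the force peaks.
#'   Defaults to [default_peak_fraction()].
#' @param shape `"brittle"` or `"ductile"`. Default depends on the food.
#' @param rise_exponent Dimensionless exponent of the pre-peak power law.
#' @param decay Post-peak envelope width as a fraction of the remaining
#'   closure `(1 - p_peak)`.
#' @param plateau Plateau level of ductile curves as a fraction of `F_peak`.
#' @return An object of class `food_curve`.
#' @examples
#' crv <- food_curve("d")
#' force_at(crv, crv$food$h_m * crv$p_peak) # peak force by construction
#' @export
food_curve <- function(food_id, F_peak = NULL, p_peak = NULL, shape = NULL,
                       rise_exponent = 2, decay = 0.25, plateau = 0.65) {
  food <- if (is.data.frame(food_id)) food_id else food_specimen(food_id)
  id <- food$id
  F_peak <- F_peak %||% default_peak_force(id)
  p_peak <- p_peak %||% default_peak_fraction(id)
  shape <- shape %||% default_shape(id)
  shape <- match.arg(shape, c("brittle", "ductile"))
  stopifnot(F_peak > 0, p_peak > 0, p_peak < 1, rise_exponent > 0, decay > 0)
  structure(
    list(
      food = food, F_peak = F_peak, p_peak = p_peak, shape = shape,
      rise_exponent = rise_exponent, decay = decay, plateau = plateau
    ),
    class = "food_curve"
  )
}

#' @export
print.food_curve <- function(x, ...) {
  cat(
    sprintf(
      "<food_curve> %s (%s): F_peak = %.1f N at %.1f %% of closure (h = %.1f mm)\n",
      x$food$label, x$shape, x$F_peak, 100 * x$p_peak, 1000 * x$food$h_m
    )
  )
  invisible(x)
}

#' Evaluate a food curve
#'
#' Deterministic evaluation of the parametric characteristic at a height
#' change `dh`. `force_at(curve, 0)` is 0 and the maximum over `[0, h]` is
#' `F_peak`, attained at `dh = p_peak * h`.
#'
#' @param curve A [food_curve()].
#' @param dh Height change(s) in metres, in `[0, h]`.
#' @return Force(s) in newtons.
#' @export
force_at <- function(curve, dh) {
  stopifnot(inherits(curve, "food_curve"))
  h <- curve$food$h_m
  if (any(dh < -1e-12 | dh > h + 1e-12)) {
    stop_chewsim(
      "dh out of range: food height is ", format(h), " m; got ",
      paste(format(dh[dh < -1e-12 | dh > h + 1e-12]), collapse = ", ")
    )
  }
  dh <- pmin(pmax(dh, 0), h)
  x <- dh / h
  p <- curve$p_peak
  g <- numeric(length(x))
  rising <- x <= p
  g[rising] <- (x[rising] / p)^curve$rise_exponent
  if (any(!rising)) {
    u <- (x[!rising] - p) / (curve$decay * (1 - p))
    env <- exp(-0.5 * u^2)
    g[!rising] <- if (curve$shape == "brittle") {
      env
    } else {
      curve$plateau + (1 - curve$plateau) * env
    }
  }
  curve$F_peak * g
}

#' Decompose a food curve into time profiles
#'
#' Composes the characteristic with a closure function `dh(t)` to obtain the
#' paired time series `F(t)` and `dh(t)` on a uniform time grid over
#' `[0, t_chew]`.
#'
#' @param curve A [food_curve()].
#' @param closure A function mapping time in seconds to height change in
#'   metres, with `closure(0) = 0`, `closure(t_chew) = h`, non-decreasing.
#'   Defaults to uniform closure at constant rate.
#' @param n_steps Number of grid intervals.
#' @param noise_sd Optional multiplicative force noise (standard deviation as
#'   a fraction of the local force), for robustness experiments only; off by
#'   default.
#' @param seed Seed used when `noise_sd > 0`.
#' @return A tibble with columns `t_s`, `dh_m`, `F_N`.
#' @export
time_profiles <- function(curve, closure = NULL, n_steps = 200,
                          noise_sd = 0, seed = NULL) {
  stopifnot(inherits(curve, "food_curve"))
  h <- curve$food$h_m
  t_chew <- curve$food$t_chew_s
  closure <- closure %||% function(t) h * t / t_chew
  t <- seq(0, t_chew, length.out = n_steps + 1)
  dh <- vapply(t, closure, numeric(1))
  if (abs(dh[1]) > 1e-9 || abs(dh[length(dh)] - h) > 1e-6 * h) {
    stop_chewsim("closure must map 0 -> 0 and t_chew -> h")
  }
  if (any(diff(dh) < -1e-12)) {
    stop_chewsim("closure must be non-decreasing over [0, t_chew]")
  }
  F <- force_at(curve, dh)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    F <- pmax(0, F * (1 + stats::rnorm(length(F), sd = noise_sd)))
  }
  tibble::tibble(t_s = t, dh_m = dh, F_N = F)
}

#' Export sampled curve points as CSV
#'
#' Writes a two-column CSV (`dh_m`, `F_N`) of the curve sampled on a uniform
#' deformation grid.
#'
#' @param curve A [food_curve()].
#' @param path Output file path.
#' @param n Number of samples.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, path, n = 201) {
  dh <- seq(0, curve$food$h_m, length.out = n)
  df <- data.frame(dh_m = dh, F_N = force_at(curve, dh))
  write_csv_commented(
    df, path,
    comment = sprintf(
      "food curve %s: dh_m (m), F_N (N); F_peak=%.4g N, p_peak=%.4g, shape=%s",
      curve$food$id, curve$F_peak, curve$p_peak, curve$shape
    )
  )
  invisible(path)
}
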