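# Stage 3: decomposition of the temporalis principal vector.
#
# The temporalis principal force is split into anterior, middle and
# posterior components in proportion to the parts' physiological
# cross-sectional areas, so the scalar magnitudes sum exactly to the
# principal magnitude. The component directions (76, 42 and 22 degrees
# above the horizontal sagittal axis, with the principal line at 58
# degrees) are carried as direction metadata; the split itself is scalar.

#' Split a temporalis principal force into its three parts
#'
#' PCSA-proportional scalar decomposition: `FAT = 0.4794 FT`,
#' `FMT = 0.2907 FT`, `FPT = 0.2299 FT`. The fractions sum to one, so the
#' components sum to the principal magnitude exactly.
#'
#' @param FT Principal temporalis force magnitude(s), N, non-negative.
#' @return A tibble with columns `FT_N`, `FAT_N`, `FMT_N`, `FPT_N` and the
#'   part direction angles (degrees above the horizontal sagittal axis) as
#'   attribute `"angles_deg"`.
#' @examples
#' split_temporalis(46.1)
#' @export
split_temporalis <- function(FT) {
  if (any(FT < 0)) stop_chewsim("temporalis force must be non-negative")
  f <- TEMPORALIS_FRACTIONS
  out <- tibble::tibble(
    FT_N = FT,
    FAT_N = f[["anterior"]] * FT,
    FMT_N = f[["middle"]] * FT,
    FPT_N = f[["posterior"]] * FT
  )
  attr(out, "angles_deg") <- FIG_ANGLES_DEG[c("theta", "gamma", "beta")]
  out
}

#' Append temporalis component series to a force solution
#'
#' @param solution A [run_forces()] solution.
#' @return The solution with columns `FAT_<side>_N`, `FMT_<side>_N`,
#'   `FPT_<side>_N` added to its series.
#' @export
augment_temporalis <- function(solution) {
  stopifnot(inherits(solution, "muscle_force_solution"))
  f <- TEMPORALIS_FRACTIONS
  s <- solution$series
  for (side in c("W", "N")) {
    ft <- s[[paste0("FT_", side, "_N")]]
    s[[paste0("FAT_", side, "_N")]] <- f[["anterior"]] * ft
    s[[paste0("FMT_", side, "_N")]] <- f[["middle"]] * ft
    s[[paste0("FPT_", side, "_N")]] <- f[["posterior"]] * ft
  }
  solution$series <- s
  solution
}
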