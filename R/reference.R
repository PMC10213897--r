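#' Bundled reference tables for unilateral chewing of five foods
#'
#' The package bundles a reference dataset from a published simulation study
#' of unilateral chewing: food specimen dimensions and chewing times, maximum
#' muscle forces with the corresponding and total contractions, muscle
#' stiffness, intrinsic strength (with the PCSA values used), the force and
#' contraction proportionality coefficients, and the non-working-side
#' condylar path lengths. These tables serve two roles: they are the
#' calibration targets for the default anatomy, and they are fixtures for the
#' arithmetic validation tier that does not depend on the geometry
#' reconstruction.
#'
#' @param table One of `"foods"`, `"max_forces_contractions"`, `"stiffness"`,
#'   `"intrinsic_strength"`, `"force_ratios"`, `"contraction_ratios"`,
#'   `"condylar_paths"`.
#' @return A tibble. Units are SI and encoded in the column names
#'   (`F_H_N` newtons, `dq_C_m` metres, `K_N_per_m` newtons per metre, ...).
#' @examples
#' reference_table("foods")
#' @export
reference_table <- function(table = c(
                              "foods", "max_forces_contractions", "stiffness",
                              "intrinsic_strength", "force_ratios",
                              "contraction_ratios", "condylar_paths"
                            )) {
  table <- match.arg(table)
  path <- system.file("extdata", "reference", paste0(table, ".csv"),
    package = "chewsim", mustWork = TRUE
  )
  read_csv_commented(path)
}

#' All bundled reference tables at once
#'
#' @return A named list of tibbles, see [reference_table()].
#' @export
reference_tables <- function() {
  nms <- c(
    "foods", "max_forces_contractions", "stiffness", "intrinsic_strength",
    "force_ratios", "contraction_ratios", "condylar_paths"
  )
  stats::setNames(lapply(nms, reference_table), nms)
}
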