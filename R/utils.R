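# Internal geometry and I/O helpers.

vec3 <- function(x, y, z) c(x = x, y = y, z = z)

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Elementary rotation matrices, right-handed, angles in radians.
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

deg2rad <- function(d) d * pi / 180

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_chewsim <- function(...) stop(paste0(...), call. = FALSE)

# Write a data frame as CSV with one leading '#' comment line carrying units
# and provenance, matching the plain-text interfaces used throughout.
write_csv_commented <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con,
    sep = ",", row.names = FALSE, quote = FALSE, na = "NA"
  )
  invisible(path)
}

read_csv_commented <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}
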