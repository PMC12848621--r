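# Mueller matrices of the elementary optical elements, and the physical
# realizability check used to guard reconstruction output.

#' Mueller matrix of an ideal linear polarizer
#'
#' @param angle Transmission-axis angle from horizontal, radians.
#' @return 4x4 Mueller matrix.
#' @export
mueller_linear_polarizer <- function(angle = 0) {
  stopifnot(is.numeric(angle), length(angle) == 1L, is.finite(angle))
  c2 <- cos(2 * angle); s2 <- sin(2 * angle)
  0.5 * matrix(c(
    1,       c2,      s2,      0,
    c2,      c2^2,    c2 * s2, 0,
    s2,      c2 * s2, s2^2,    0,
    0,       0,       0,       0
  ), 4, 4, byrow = TRUE)
}

#' Mueller matrix of a linear retarder
#'
#' Retarder with retardance `retardance` and fast axis at `fast_axis` from
#' horizontal.  Leaves total intensity unchanged; its lower-right 3x3 block
#' is a rotation (determinant 1).  Sign convention: a quarter-wave plate at
#' 45 deg maps horizontal polarization `(1,1,0,0)` to right circular
#' `(1,0,0,1)`.
#'
#' @param retardance Retardance in radians, in `[0, 2*pi)`.
#' @param fast_axis Fast-axis angle in radians.
#' @return 4x4 Mueller matrix.
#' @export
mueller_retarder <- function(retardance, fast_axis = 0) {
  stopifnot(is.numeric(retardance), length(retardance) == 1L,
            retardance >= 0, retardance < 2 * pi,
            is.numeric(fast_axis), length(fast_axis) == 1L)
  cd <- cos(retardance); sd <- sin(retardance)
  c2 <- cos(2 * fast_axis); s2 <- sin(2 * fast_axis)
  matrix(c(
    1, 0,                      0,                      0,
    0, c2^2 + s2^2 * cd,       c2 * s2 * (1 - cd),     -s2 * sd,
    0, c2 * s2 * (1 - cd),     s2^2 + c2^2 * cd,        c2 * sd,
    0, s2 * sd,                -c2 * sd,                cd
  ), 4, 4, byrow = TRUE)
}

#' Mueller matrix of a diagonal depolarizer
#'
#' `diag(1, a, b, c)`: retains a fraction `a` of the H/V linear component,
#' `b` of the +/-45 deg linear component and `c` of the circular component.
#'
#' @param a,b,c Retention factors, each in `[-1, 1]`.
#' @return 4x4 Mueller matrix.
#' @export
mueller_depolarizer <- function(a, b = a, c = a) {
  f <- c(a, b, c)
  if (!is.numeric(f) || length(f) != 3L || any(!is.finite(f)) || any(abs(f) > 1))
    stop("depolarizer retention factors must be finite and in [-1, 1]")
  diag(c(1, f))
}

#' Mueller matrix of a pure diattenuator
#'
#' Builds the normalized diattenuator with diattenuation vector `d`
#' (length-3, `|d| <= 1`):
#' first row/column `(1, d)`, lower 3x3 block
#' `sqrt(1 - D^2) I + (1 - sqrt(1 - D^2)) dhat dhat^T`.
#'
#' @param d Diattenuation vector, numeric length 3 with norm at most 1.
#' @return 4x4 Mueller matrix with `m11 = 1`.
#' @export
mueller_diattenuator <- function(d) {
  stopifnot(is.numeric(d), length(d) == 3L, all(is.finite(d)))
  D <- sqrt(sum(d^2))
  if (D > 1) stop("diattenuation vector norm exceeds 1")
  m <- diag(4)
  m[1, 2:4] <- d
  m[2:4, 1] <- d
  if (D > 0) {
    dhat <- d / D
    sq <- sqrt(1 - D^2)
    m[2:4, 2:4] <- sq * diag(3) + (1 - sq) * tcrossprod(dhat)
  }
  m
}

#' Physical-realizability check for a Mueller matrix
#'
#' Performs fast necessary checks on a (possibly noisy) Mueller matrix:
#' `m11 > 0`, `|m[i,j]| <= m11 * (1 + tol)` for all elements, and
#' `tr(M^T M) <= 4 * m11^2 * (1 + tol)`.  Diagnostic only - never raises.
#'
#' @param m 4x4 Mueller matrix.
#' @param tol Relative tolerance.  The default `1e-9` suits noiseless
#'   synthetic matrices; use a looser profile (e.g. `1e-2`) for noisy
#'   reconstructions, where valid pixels sit slightly outside the bounds.
#' @return A list with `pass` (logical) and `violations` (character vector
#'   naming each violated condition, empty when `pass` is `TRUE`).
#' @export
is_physical <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)), is.numeric(m))
  v <- character(0)
  if (!all(is.finite(m))) {
    v <- c(v, "non-finite elements")
    return(list(pass = FALSE, violations = v))
  }
  m11 <- m[1, 1]
  if (m11 <= 0) v <- c(v, "m11 > 0")
  else {
    if (any(abs(m) > m11 * (1 + tol)))
      v <- c(v, "|m_ij| <= m11")
    if (sum(m^2) > 4 * m11^2 * (1 + tol))
      v <- c(v, "tr(M^T M) <= 4 m11^2")
  }
  list(pass = length(v) == 0L, violations = v)
}

#' Write / read a Mueller matrix as a CSV block
#'
#' Serializes a single 4x4 Mueller matrix to CSV with row and column headers
#' `m1..m4`, the fixture format used in tests.
#'
#' @param m 4x4 Mueller matrix.
#' @param path File path.
#' @return `write_mueller_csv` returns `path` invisibly;
#'   `read_mueller_csv` returns the 4x4 matrix.
#' @export
write_mueller_csv <- function(m, path) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  dimnames(m) <- list(paste0("m", 1:4), paste0("m", 1:4))
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_mueller_csv
#' @export
read_mueller_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1)
  m <- as.matrix(df)
  stopifnot(all(dim(m) == c(4L, 4L)))
  dimnames(m) <- NULL
  m
}
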