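#' Polarization state labels
#'
#' The six fully polarized states used by the measurement scheme:
#' `H` (horizontal), `V` (vertical), `P` (+45 deg linear), `M` (-45 deg
#' linear), `R` (right circular) and `L` (left circular).
#'
#' @format Character vector of length six.
#' @export
POL_STATES <- c("H", "V", "P", "M", "R", "L")

# Unit-intensity Stokes vectors of the six states, one per column.
# Circular sign convention: R (right circular) carries s3 = +1.  Any
# consistent convention gives identical reconstructions; this one is fixed
# package-wide and shared by the forward model and the tests.
.STATE_STOKES <- cbind(
  H = c(1,  1,  0,  0),
  V = c(1, -1,  0,  0),
  P = c(1,  0,  1,  0),
  M = c(1,  0, -1,  0),
  R = c(1,  0,  0,  1),
  L = c(1,  0,  0, -1)
)

#' Stokes vector of a polarization state
#'
#' Returns the unit-intensity, fully polarized Stokes vector
#' `(s0, s1, s2, s3)` of one of the six generator/analyzer states.
#'
#' @param state A single state label, one of `"H"`, `"V"`, `"P"`, `"M"`,
#'   `"R"`, `"L"`.
#' @return Numeric vector of length 4 in intensity units with `s0 = 1`.
#' @examples
#' stokes_of_state("H")   # c(1, 1, 0, 0)
#' stokes_of_state("R")   # c(1, 0, 0, 1)
#' @export
stokes_of_state <- function(state) {
  if (!is.character(state) || length(state) != 1L || !(state %in% POL_STATES))
    stop("unknown polarization state ", deparse(state),
         "; admissible labels are ", paste(POL_STATES, collapse = ", "))
  .STATE_STOKES[, state]
}

#' Degree of polarization
#'
#' `sqrt(s1^2 + s2^2 + s3^2) / s0` of a Stokes vector; 1 for fully polarized
#' light, 0 for unpolarized light.
#'
#' @param s Stokes vector, numeric length 4 with `s[1] > 0`.
#' @return Scalar in `[0, 1]` for physical light.
#' @export
degree_of_polarization <- function(s) {
  stopifnot(is.numeric(s), length(s) == 4L, s[1] > 0)
  sqrt(sum(s[2:4]^2)) / s[1]
}

#' Apply a Mueller matrix to a Stokes vector
#'
#' Computes the output Stokes vector `S_out = M %*% S_in`, the fundamental
#' Stokes-Mueller relation.
#'
#' @param m 4x4 real Mueller matrix.
#' @param s_in Input Stokes vector, numeric length 4.
#' @return Output Stokes vector, numeric length 4.
#' @export
apply_mueller <- function(m, s_in) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)),
            is.numeric(s_in), length(s_in) == 4L)
  drop(m %*% s_in)
}

#' Detected intensity behind an ideal analyzer
#'
#' Intensity measured when the beam described by Stokes vector `s` passes an
#' ideal polarization analyzer set to one of the six states:
#' `0.5 * (s0 + a . (s1, s2, s3))` where `a` is the polarized part of the
#' analyzer state.
#'
#' @param analyzer Analyzer state label (see [POL_STATES]).
#' @param s Stokes vector of the analyzed beam.
#' @return Nonnegative scalar intensity (same units as `s[1]`).
#' @export
analyzer_intensity <- function(analyzer, s) {
  a <- stokes_of_state(analyzer)
  stopifnot(is.numeric(s), length(s) == 4L)
  0.5 * (s[1] + sum(a[2:4] * s[2:4]))
}
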