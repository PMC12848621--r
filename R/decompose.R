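# Lu-Chipman polar decomposition M = M_Delta %*% M_R %*% M_D of a normalized
# Mueller matrix into depolarizer, retarder and diattenuator factors, and the
# scalar parameter maps D, P, R, Delta derived from it.

#' Diattenuation of a Mueller matrix
#'
#' `D = sqrt(m12^2 + m13^2 + m14^2) / m11`, the first-row measure of
#' differential transmission of orthogonal polarization states.
#'
#' @param m 4x4 Mueller matrix with `m11 != 0`.
#' @return Scalar diattenuation, in `[0, 1]` for physical matrices.
#' @export
diattenuation <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  if (!is.finite(m[1, 1]) || m[1, 1] == 0)
    stop("m11 must be finite and nonzero")
  sqrt(sum(m[1, 2:4]^2)) / m[1, 1]
}

#' Polarizance of a Mueller matrix
#'
#' `P = sqrt(m21^2 + m31^2 + m41^2) / m11`, the first-column measure of the
#' polarization imparted to unpolarized input.
#'
#' @inheritParams diattenuation
#' @return Scalar polarizance, in `[0, 1]` for physical matrices.
#' @export
polarizance <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  if (!is.finite(m[1, 1]) || m[1, 1] == 0)
    stop("m11 must be finite and nonzero")
  sqrt(sum(m[2:4, 1]^2)) / m[1, 1]
}

# Inverse with singular values floored at eps (regularized for the
# near-singular diattenuator and depolarizer factors).
.reg_inverse <- function(m, eps) {
  sv <- svd(m)
  sv$v %*% (t(sv$u) / pmax(sv$d, eps))
}

#' Lu-Chipman polar decomposition of a Mueller matrix
#'
#' Factorizes a normalized Mueller matrix as
#' `M = M_Delta %*% M_R %*% M_D` (depolarizer, retarder, diattenuator, the
#' canonical factor order) and extracts the scalar parameters
#' * `D` - diattenuation (first row),
#' * `P` - polarizance (first column),
#' * `R` - retardance in radians, `acos((tr(m_R) + 1)/2 - 1)` in `[0, pi]`,
#' * `Delta` - depolarization power `1 - |tr(m_Delta)| / 3` in `[0, 1]`,
#'
#' where `m_R`, `m_Delta` are the 3x3 blocks of the retarder and depolarizer
#' factors.  The depolarizer block is the symmetric square root of
#' `m' m'^T` (with `m'` the 3x3 block of `M %*% solve(M_D)`), signed by
#' `sign(det m')`; its eigenvalues are clamped at zero before the square
#' root, a numerical guard that noise can trigger (status `"clamped"`).
#' A polarizer-like input with `D >= 1 - eps` is handled through a
#' regularized inverse of `M_D` (status `"singular_diattenuator"`) so that
#' image-scale runs never crash on such pixels.
#'
#' @param m Normalized 4x4 Mueller matrix (`m11 = 1`), all elements finite.
#' @param eps Threshold for the singular-diattenuator branch and floor added
#'   to deficient singular values in the regularized inverses.
#' @return A list of class `"mm_decomposition"` with elements `D`, `P`, `R`,
#'   `Delta`, the factor matrices `M_D`, `M_R`, `M_Delta`, and `status`
#'   (one of `"ok"`, `"singular_diattenuator"`, `"clamped"`).
#' @references Lu & Chipman, J. Opt. Soc. Am. A 13, 1106 (1996).
#' @export
decompose_mueller <- function(m, eps = 1e-6) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  if (!all(is.finite(m))) stop("Mueller matrix contains non-finite elements")
  if (abs(m[1, 1] - 1) > 1e-8)
    stop("`m` must be m11-normalized (m11 = 1); got m11 = ", m[1, 1])

  d <- m[1, 2:4]
  D <- sqrt(sum(d^2))
  P <- sqrt(sum(m[2:4, 1]^2))
  status <- "ok"

  M_D <- mueller_diattenuator(if (D > 1) d / D else d)
  if (D >= 1 - eps) {
    status <- "singular_diattenuator"
    MDinv <- .reg_inverse(M_D, eps)
  } else {
    MDinv <- solve(M_D)
  }

  Mp <- m %*% MDinv
  mp <- Mp[2:4, 2:4]

  S <- mp %*% t(mp)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- ev$values
  if (any(lam < 0)) {
    if (any(lam < -eps)) status <- if (status == "ok") "clamped" else status
    lam <- pmax(lam, 0)
  }
  sgn <- sign(det(mp))
  if (sgn == 0) sgn <- 1
  m_delta <- sgn * ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  Delta <- 1 - abs(sum(diag(m_delta))) / 3

  m_r <- .reg_inverse(m_delta, eps) %*% mp
  R <- acos(min(1, max(-1, (sum(diag(m_r)) + 1) / 2 - 1)))

  M_R <- diag(4); M_R[2:4, 2:4] <- m_r
  M_Delta <- diag(4)
  M_Delta[2:4, 1] <- Mp[2:4, 1]
  M_Delta[2:4, 2:4] <- m_delta

  structure(list(D = D, P = P, R = R, Delta = Delta,
                 M_D = M_D, M_R = M_R, M_Delta = M_Delta, status = status),
            class = "mm_decomposition")
}

#' @export
print.mm_decomposition <- function(x, ...) {
  cat(sprintf(
    "Lu-Chipman decomposition [%s]: D = %.4f, P = %.4f, R = %.4f rad, Delta = %.4f\n",
    x$status, x$D, x$P, x$R, x$Delta))
  invisible(x)
}

#' Pixelwise Lu-Chipman decomposition of a Mueller image
#'
#' Applies [decompose_mueller()] at every masked-in pixel of a normalized
#' Mueller image (compiled inner loop), producing one scalar map per
#' parameter.  Masked-out pixels carry `NA`.
#'
#' @param img A normalized `"mueller_image"`.
#' @param eps Singular-branch threshold, as in [decompose_mueller()].
#' @return An object of class `"decomposition_maps"`: matrices `D`, `P`,
#'   `R`, `Delta`, the inherited `mask` and `meta`, and `log`, a list with
#'   the per-image counts `n_singular` and `n_clamped`.
#' @export
decompose_image <- function(img, eps = 1e-6) {
  if (!inherits(img, "mueller_image")) stop("`img` must be a mueller_image")
  if (!img$normalized) stop("`img` must be m11-normalized; see normalize_by_m11()")
  d <- dim(img$elements)
  res <- cpp_decompose_image(img$elements, img$mask, eps)
  maps <- lapply(res[c("D", "P", "R", "Delta")], function(v)
    matrix(v, d[1], d[2]))
  structure(list(D = maps$D, P = maps$P, R = maps$R, Delta = maps$Delta,
                 mask = img$mask, meta = img$meta,
                 log = list(n_singular = res$n_singular,
                            n_clamped = res$n_clamped)),
            class = "decomposition_maps")
}

#' @export
print.decomposition_maps <- function(x, ...) {
  cat(sprintf("decomposition_maps: %d x %d px, %d masked in (%d singular, %d clamped)\n",
              nrow(x$D), ncol(x$D), sum(x$mask),
              x$log$n_singular, x$log$n_clamped))
  invisible(x)
}
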