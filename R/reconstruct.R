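# Reconstruction of the per-pixel Mueller matrix image from the 36
# polarization-resolved intensity images of the six-state scheme.

# State pairs and signs entering each element plane.  The generator state
# (first letter of an intensity key) selects the column combination, the
# analyzer state (second letter) the row combination:
#   1: H + V,  2: H - V,  3: P - M,  4: R - L
# so e.g. the m12 plane is HH + HV - VH - VV and m44 is RR - RL - LR + LL.
.COMBO <- list(
  list(states = c("H", "V"), signs = c(1,  1)),
  list(states = c("H", "V"), signs = c(1, -1)),
  list(states = c("P", "M"), signs = c(1, -1)),
  list(states = c("R", "L"), signs = c(1, -1))
)

#' All 36 generator/analyzer state pairs
#'
#' Keys are two-letter strings, first letter the generator (PSG) state,
#' second the analyzer (PSA) state, e.g. `"HV"` = generated H, analyzed V.
#'
#' @return Character vector of the 36 ordered state-pair keys.
#' @export
state_pairs <- function() {
  as.vector(t(outer(POL_STATES, POL_STATES, paste0)))
}

#' Bundle 36 intensity images into a measurement stack
#'
#' @param images Named list of 36 nonnegative numeric matrices, one per
#'   generator/analyzer pair, named as in [state_pairs()].
#' @param meta List of sample metadata; recognized fields are `sample_id`,
#'   `age_days`, `wavelength_nm` (one of 445, 532, 632) and `preparation`
#'   (one of `"no_paraffin"`, `"paraffin"`, `"ffpe_block"`).
#' @return An object of class `"intensity_stack"`.
#' @export
intensity_stack <- function(images, meta = list()) {
  wanted <- state_pairs()
  missing <- setdiff(wanted, names(images))
  if (length(missing))
    stop("intensity stack is missing state pair(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(images), wanted)
  if (length(extra))
    stop("unknown state pair(s): ", paste(extra, collapse = ", "))
  images <- images[wanted]
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all 36 images must share one shape")
  if (any(vapply(images, function(x) any(x < 0), logical(1))))
    stop("intensity images must be nonnegative")
  structure(list(images = images, meta = meta), class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("intensity_stack: 36 images, %d x %d px\n", d[1], d[2]))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.new_mueller_image <- function(elements, normalized, mask, meta) {
  structure(list(elements = elements, normalized = normalized,
                 mask = mask, meta = meta),
            class = "mueller_image")
}

#' @export
print.mueller_image <- function(x, ...) {
  d <- dim(x$elements)
  cat(sprintf("mueller_image: %d x %d px, %s, %d/%d pixels masked in\n",
              d[1], d[2],
              if (x$normalized) "m11-normalized" else "unnormalized",
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Reconstruct the Mueller-matrix image from a 36-state stack
#'
#' Evaluates, pixelwise, the sixteen four-term signed sums of the six-state
#' reconstruction scheme (e.g. the m11 plane is `HH + HV + VH + VV`, the m44
#' plane `RR - RL - LR + LL`; first letter generator, second analyzer).  For
#' a stack synthesized through ideal states from a sample matrix `M` the
#' result is exactly `2 * M` per pixel; the scale is removed by
#' [normalize_by_m11()].
#'
#' @param stack An [intensity_stack()].
#' @return An unnormalized `"mueller_image"`: element array of dimension
#'   `(rows, cols, 4, 4)`, an all-true validity mask and the stack metadata.
#' @export
reconstruct_mueller <- function(stack) {
  if (!inherits(stack, "intensity_stack"))
    stop("`stack` must be an intensity_stack")
  d <- dim(stack$images[[1]])
  el <- array(0, c(d[1], d[2], 4L, 4L))
  for (i in 1:4) {
    for (j in 1:4) {
      acc <- matrix(0, d[1], d[2])
      gj <- .COMBO[[j]]; ai <- .COMBO[[i]]
      for (g in 1:2) for (a in 1:2) {
        key <- paste0(gj$states[g], ai$states[a])
        acc <- acc + gj$signs[g] * ai$signs[a] * stack$images[[key]]
      }
      el[, , i, j] <- acc
    }
  }
  .new_mueller_image(el, normalized = FALSE,
                     mask = matrix(TRUE, d[1], d[2]), meta = stack$meta)
}

#' Normalize a Mueller image by its m11 element
#'
#' Divides every element plane pixelwise by the m11 plane, masking out
#' pixels whose m11 falls at or below `floor * max(m11)` (noise-dominated
#' division guard).  Masked-out pixels carry `NA` in all 16 planes.
#'
#' @param img Unnormalized `"mueller_image"`.
#' @param floor Masking floor as a fraction of the image's m11 maximum,
#'   in (0, 1).  Default 0.01.
#' @return A normalized `"mueller_image"` with `m11 = 1` at masked-in pixels.
#' @export
normalize_by_m11 <- function(img, floor = 0.01) {
  if (!inherits(img, "mueller_image")) stop("`img` must be a mueller_image")
  if (img$normalized) stop("`img` is already normalized")
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0 || floor >= 1)
    stop("`floor` must be a fraction in (0, 1)")
  m11 <- img$elements[, , 1, 1]
  keep <- img$mask & is.finite(m11) & (m11 > floor * max(m11, na.rm = TRUE))
  el <- img$elements
  m11[!keep] <- NA_real_
  for (i in 1:4) for (j in 1:4) el[, , i, j] <- el[, , i, j] / m11
  .new_mueller_image(el, normalized = TRUE, mask = keep, meta = img$meta)
}

#' Region-of-interest mask from the m11 plane
#'
#' Selects tissue pixels from the unpolarized-transmission (m11) plane,
#' combined (logical AND) with the image's validity mask.  The statistics
#' of parameter maps are computed over this region; the rule is explicit
#' and configurable because segmentation conventions differ between
#' instruments.
#'
#' @param img A `"mueller_image"` (normalized or not; the m11 plane of a
#'   normalized image is reconstructed from its mask).
#' @param method `"percentile"` keeps pixels with m11 above the `param`-th
#'   percentile of the image; `"fixed"` keeps pixels with
#'   `m11 >= param * max(m11)`.
#' @param param Percentile in `[0, 100)` or fraction in `[0, 1]`,
#'   respectively.  Default: 50th percentile.
#' @param m11 Optional m11 plane to threshold on (required if `img` is
#'   normalized, where the stored m11 plane is constant 1).
#' @return Logical matrix, `TRUE` at region-of-interest pixels.
#' @export
tissue_mask <- function(img, method = c("percentile", "fixed"), param = 50,
                        m11 = NULL) {
  if (!inherits(img, "mueller_image")) stop("`img` must be a mueller_image")
  method <- match.arg(method)
  if (is.null(m11)) {
    if (img$normalized)
      stop("`img` is normalized; supply the unnormalized m11 plane via `m11`")
    m11 <- img$elements[, , 1, 1]
  }
  stopifnot(all(dim(m11) == dim(img$mask)))
  if (all(!is.finite(m11)) || max(m11, na.rm = TRUE) <= 0) {
    warning("m11 plane carries no signal; returning an empty mask")
    return(matrix(FALSE, nrow(m11), ncol(m11)))
  }
  keep <- switch(method,
    percentile = {
      if (param < 0 || param >= 100)
        stop("percentile `param` must be in [0, 100)")
      thr <- stats::quantile(m11, probs = param / 100, na.rm = TRUE,
                             names = FALSE, type = 7)
      m11 >= thr
    },
    fixed = {
      if (param < 0 || param > 1)
        stop("fixed-threshold `param` must be in [0, 1]")
      m11 >= param * max(m11, na.rm = TRUE)
    }
  )
  keep[!is.finite(m11)] <- FALSE
  keep & img$mask
}

#' Extract one element plane of a Mueller image
#'
#' @param img A `"mueller_image"`.
#' @param i,j 1-based element indices (`i = 2, j = 2` gives the m22 plane).
#' @return Numeric matrix; masked-out pixels are `NA`.
#' @export
mm_element <- function(img, i, j) {
  stopifnot(inherits(img, "mueller_image"),
            i %in% 1:4, j %in% 1:4)
  img$elements[, , i, j]
}
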