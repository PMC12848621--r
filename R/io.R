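# File interchange: intensity stacks as per-state 16-bit TIFFs with a YAML
# metadata sidecar, Mueller images and parameter maps as multi-plane TIFFs.
#
# Storage contract: the tiff writer quantizes to unsigned integers in [0, 1],
# so every image is written with an explicit linear scale recorded in the
# sidecar.  16-bit intensity data with integer values round-trips exactly;
# 32-bit parameter maps round-trip to ~2e-10 relative.

.ELEMENT_ORDER <- as.vector(t(outer(1:4, 1:4,
                                    function(i, j) paste0("m", i, j))))

#' Write an intensity stack to disk
#'
#' Writes 36 single-channel 16-bit TIFFs named
#' `<sample_id>_<G><A>.tif` (generator letter first) plus a `meta.yaml`
#' recording the metadata and the intensity scale (counts per stored unit).
#'
#' @param stack An [intensity_stack()].
#' @param dir Output directory (created if needed).
#' @param bits 8, 16 or 32 bits per sample.
#' @return The directory path, invisibly.
#' @export
write_stack <- function(stack, dir, bits = 16L) {
  stopifnot(inherits(stack, "intensity_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- stack$meta$sample_id
  if (is.null(id)) id <- "sample"
  mx <- max(vapply(stack$images, max, 0), 1e-12)
  scale <- mx   # stored value 1.0 corresponds to `scale` counts
  for (key in names(stack$images)) {
    tiff::writeTIFF(stack$images[[key]] / scale,
                    file.path(dir, sprintf("%s_%s.tif", id, key)),
                    bits.per.sample = as.integer(bits))
  }
  meta <- stack$meta
  meta$intensity_scale <- scale
  meta$bits_per_sample <- as.integer(bits)
  meta$file_pattern <- sprintf("%s_{G}{A}.tif", id)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read an intensity stack from disk
#'
#' Reads the 36 per-state TIFFs and `meta.yaml` written by [write_stack()]
#' (or by the measurement software, following the same layout).  Stored
#' values are promoted to floating point and multiplied by the recorded
#' `intensity_scale` (scale 1 if absent).
#'
#' @param dir Sample directory containing the images and `meta.yaml`.
#' @return An [intensity_stack()].
#' @export
read_stack <- function(dir) {
  metafile <- file.path(dir, "meta.yaml")
  if (!file.exists(metafile)) stop("no meta.yaml in ", dir)
  meta <- yaml::read_yaml(metafile)
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  id <- if (is.null(meta$sample_id)) "sample" else meta$sample_id
  images <- list()
  for (key in state_pairs()) {
    f <- file.path(dir, sprintf("%s_%s.tif", id, key))
    if (!file.exists(f))
      stop("missing intensity image for state pair ", key, ": ", f)
    img <- tiff::readTIFF(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    images[[key]] <- img * scale
  }
  meta$intensity_scale <- NULL
  meta$bits_per_sample <- NULL
  meta$file_pattern <- NULL
  intensity_stack(images, meta = meta)
}

#' Write a Mueller image as a multi-plane TIFF
#'
#' Writes the 16 element planes (order m11, m12, ..., m44) plus one mask
#' plane as a 17-plane 32-bit TIFF; element range and order are recorded in
#' a YAML sidecar.
#'
#' @param img A `"mueller_image"`.
#' @param path Output TIFF path (sidecar gets extension `.yaml`).
#' @return `path`, invisibly.
#' @export
write_mueller_tiff <- function(img, path) {
  stopifnot(inherits(img, "mueller_image"))
  el <- img$elements
  lo <- min(el, na.rm = TRUE); hi <- max(el, na.rm = TRUE)
  if (hi <= lo) hi <- lo + 1
  planes <- vector("list", 17L)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1L
    p <- (el[, , i, j] - lo) / (hi - lo)
    p[!img$mask] <- 0
    planes[[k]] <- p
  }
  planes[[17L]] <- matrix(as.numeric(img$mask), nrow(img$mask))
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  yaml::write_yaml(c(img$meta,
                     list(plane_order = c(.ELEMENT_ORDER, "mask"),
                          value_offset = lo, value_range = hi - lo,
                          normalized = img$normalized)),
                   paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}

#' Read a Mueller image written by [write_mueller_tiff()]
#'
#' @param path TIFF path (with YAML sidecar alongside).
#' @return A `"mueller_image"`.
#' @export
read_mueller_tiff <- function(path) {
  side <- yaml::read_yaml(paste0(tools::file_path_sans_ext(path), ".yaml"))
  planes <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(planes) == 17L)
  mask <- planes[[17L]] > 0.5
  d <- dim(mask)
  el <- array(NA_real_, c(d[1], d[2], 4L, 4L))
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1L
    p <- planes[[k]] * side$value_range + side$value_offset
    p[!mask] <- NA_real_
    el[, , i, j] <- p
  }
  meta <- side[setdiff(names(side),
                       c("plane_order", "value_offset", "value_range",
                         "normalized"))]
  .new_mueller_image(el, normalized = isTRUE(side$normalized),
                     mask = mask, meta = meta)
}

#' Write decomposition maps as single-plane TIFFs
#'
#' One 32-bit TIFF per scalar map (`<stem>_D.tif`, `_P`, `_R`, `_Delta`)
#' with the value conventions in `<stem>_maps.yaml`.
#'
#' @param maps A `"decomposition_maps"`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_maps <- function(maps, stem) {
  stopifnot(inherits(maps, "decomposition_maps"))
  ranges <- list(D = 1, P = 1, R = pi, Delta = 1)
  for (p in names(ranges)) {
    v <- maps[[p]] / ranges[[p]]
    v[!is.finite(v)] <- 0
    tiff::writeTIFF(pmin(pmax(v, 0), 1),
                    sprintf("%s_%s.tif", stem, p), bits.per.sample = 32L)
  }
  yaml::write_yaml(c(maps$meta, list(
    maps = names(ranges),
    value_range = ranges,
    units = list(D = "unitless", P = "unitless", R = "radians",
                 Delta = "unitless"),
    masked_value = 0)),
    sprintf("%s_maps.yaml", stem))
  invisible(stem)
}

#' Write per-sample moment summaries as CSV
#'
#' One row per sample and parameter: sample_id, age_days, wavelength_nm,
#' preparation, parameter, mean, std, skewness, kurtosis, n_pixels.
#'
#' @param moments Data frame of stacked [central_moments()] rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_moments_csv <- function(moments, path) {
  first <- intersect(c("sample_id", "age_days", "wavelength_nm",
                       "preparation", "parameter"), names(moments))
  rest <- setdiff(names(moments), first)
  utils::write.csv(moments[, c(first, rest)], path, row.names = FALSE)
  invisible(path)
}

#' Write fitted trends as CSV
#'
#' One row per parameter, moment and fit coefficient.
#'
#' @param trends Named list of `"group_trend"` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trends_csv <- function(trends, path) {
  rows <- list()
  for (tr in trends) {
    for (mo in names(tr$fits)) {
      f <- tr$fits[[mo]]
      if (is.null(f$params)) next
      for (pn in names(f$params)) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = tr$parameter, moment = mo, model = f$model,
          coef = pn, value = unname(f$params[[pn]]),
          residual_norm = f$residual_norm,
          converged = isTRUE(f$converged), stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
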