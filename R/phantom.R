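# Synthetic tissue-phantom generator.  Produces ground-truth normalized
# Mueller-matrix maps whose scattering regime shifts from Rayleigh-like
# background toward Mie-like plaque inclusions as an "age" parameter grows,
# then simulates the 36-state measurement with noise.
#
# Per-pixel effective model (exactly the canonical polar-decomposition form,
# so the true parameter maps are available in closed form):
#   M = diag(1, a1, a2, c) %*% M_retarder(delta, theta) %*% M_diattenuator(D)
# with channel retentions a1 (H/V linear -> m22), a2 (45-deg linear -> m33)
# and c (circular -> m44).  Tissue classes:
#   background  a = (0.80, 0.80, 0.60)   Rayleigh-like, m22 ~ m33 > m44
#   plaque core c = 0.92, a2 chosen Delta-neutral    Mie-like, m44 >= m22
#   plaque rim  extra depolarization (Delta + dB)    the skewness tail
#   patches     symmetric +/- offsets on (a2, c)     growing heterogeneity
# Truncated jitters guarantee the core ordering m44 >= m22 and the
# background/rim ordering m22 > m44 at every generated pixel.

# run expr with a local RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# truncated gaussian jitter
.jitter <- function(n, sd, clamp) pmin(clamp, pmax(-clamp, stats::rnorm(n, 0, sd)))

#' Plaque density schedule
#'
#' Expected plaque count density as a function of animal age: zero before
#' the onset of plaque deposition at 45 days, then linear,
#' `kappa * max(0, age_days - 45)` plaques per 1e4 tissue pixels.
#'
#' @param age_days Age in days (scalar or vector), nonnegative.
#' @param kappa Density growth rate, plaques per 1e4 px^2 per day.
#' @return Expected plaques per 1e4 tissue pixels.
#' @export
default_age_schedule <- function(age_days, kappa = 0.16) {
  stopifnot(is.numeric(age_days), all(age_days >= 0))
  kappa * pmax(0, age_days - 45)
}

#' Specification of a synthetic tissue phantom
#'
#' Collects every parameter of one synthetic sample.  Defaults emulate the
#' study conditions: background retentions `(0.80, 0.80, 0.60)` (circular
#' depolarized faster than linear, the Rayleigh signature), Mie-like plaque
#' cores with circular retention 0.92, a depolarizing rim around each core,
#' symmetric heterogeneity patches whose coverage grows with age, plaque
#' count density following [default_age_schedule()] and plaque radius
#' maturing from 1.2 px (75 d) to 2.2 px (225 d).
#'
#' @param shape Image shape `c(rows, cols)`.
#' @param age_days Animal age in days.
#' @param wavelength_nm One of 445, 532, 632.  Shorter wavelengths sit
#'   deeper in the Rayleigh regime: the background circular retention is
#'   0.54/0.57/0.60 at 445/532/632 nm.
#' @param preparation `"no_paraffin"`, `"paraffin"` or `"ffpe_block"`.
#'   Paraffin embedding is emulated as a global retention scaling
#'   (`paraffin_scale`, default 0.85) applied to all tissue retentions.
#' @param sample_id Sample identifier string.
#' @param seed Integer seed; identical specs generate identical phantoms.
#' @param tissue_axes Ellipse semi-axes of the tissue footprint as fractions
#'   of the image dimensions.
#' @param background,core_c,rim_c_drop Channel retentions: background
#'   `(a1, a2, c)`; core circular retention; rim circular drop below
#'   background.
#' @param rim_delta,rim_delta_growth Rim depolarization contrast at 75 d and
#'   its linear growth to 225 d.
#' @param rim_width_px Rim shell width in pixels.
#' @param kappa Plaque density rate, see [default_age_schedule()].
#' @param plaque_radius_px,plaque_radius_growth Core radius at 75 d (px) and
#'   its linear growth to 225 d.
#' @param patch_coverage,patch_coverage_growth Heterogeneity patch area
#'   fraction at 75 d and linear growth to 225 d.
#' @param patch_a2,patch_c Patch offset amplitudes on the a2 and c channels.
#' @param patch_radius_px Patch disk radius.
#' @param retardance,diattenuation Background retarder (radians, fast axis
#'   horizontal) and diattenuator (along H) magnitudes.
#' @param jitter_a,jitter_c,jitter_c_core Jitter standard deviations
#'   (clamped at 0.04, 0.08 and 0.025 respectively).
#' @param mount_retention,mount_transmittance Retention and transmittance of
#'   the surrounding mount medium outside the tissue footprint.
#' @param noise_snr Default signal-to-noise ratio used by
#'   [forward_measure()] (`Inf` = noiseless).
#' @return Object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(256L, 256L),
                         age_days = 75L,
                         wavelength_nm = 632L,
                         preparation = c("no_paraffin", "paraffin", "ffpe_block"),
                         sample_id = sprintf("phantom_a%03d", age_days),
                         seed = 1L,
                         tissue_axes = c(0.42, 0.42),
                         background = c(0.80, 0.80, 0.60),
                         core_c = 0.92,
                         rim_c_drop = 0.05,
                         rim_delta = 0.06,
                         rim_delta_growth = 0.03,
                         rim_width_px = 2,
                         kappa = 0.16,
                         plaque_radius_px = 1.2,
                         plaque_radius_growth = 1.0,
                         patch_coverage = 0.15,
                         patch_coverage_growth = 0.13,
                         patch_a2 = 0.09,
                         patch_c = 0.07,
                         patch_radius_px = 4,
                         retardance = 0.30,
                         diattenuation = 0.12,
                         jitter_a = 0.015,
                         jitter_c = 0.03,
                         jitter_c_core = 0.01,
                         mount_retention = 0.05,
                         mount_transmittance = 0.25,
                         paraffin_scale = 0.85,
                         noise_snr = 50) {
  preparation <- match.arg(preparation)
  if (!wavelength_nm %in% c(445L, 532L, 632L))
    stop("wavelength_nm must be one of 445, 532, 632")
  stopifnot(age_days >= 0, length(shape) == 2L, all(shape >= 16),
            all(background > 0 & background <= 1),
            core_c > 0 && core_c <= 1,
            retardance >= 0, retardance < 2 * pi,
            diattenuation >= 0, diattenuation < 1,
            noise_snr > 0)
  # wavelength sets the depth of the Rayleigh regime via the background
  # circular retention
  c_bg <- switch(as.character(wavelength_nm),
                 "445" = 0.54, "532" = 0.57, "632" = background[3])
  r_px <- plaque_radius_px +
    plaque_radius_growth * max(0, age_days - 75) / 150
  if (2 * (r_px + rim_width_px) >= min(shape) * min(tissue_axes))
    stop("plaque radius exceeds the tissue footprint")
  spec <- list(shape = as.integer(shape), age_days = as.integer(age_days),
               wavelength_nm = as.integer(wavelength_nm),
               preparation = preparation, sample_id = sample_id,
               seed = as.integer(seed),
               tissue_axes = tissue_axes,
               background = c(background[1:2], c_bg),
               core_c = core_c, rim_c_drop = rim_c_drop,
               rim_delta = rim_delta, rim_delta_growth = rim_delta_growth,
               rim_width_px = rim_width_px, kappa = kappa,
               plaque_radius_px = r_px,
               patch_coverage = min(0.45, patch_coverage +
                 patch_coverage_growth * max(0, age_days - 75) / 150),
               patch_a2 = patch_a2, patch_c = patch_c,
               patch_radius_px = patch_radius_px,
               retardance = retardance, diattenuation = diattenuation,
               jitter_a = jitter_a, jitter_c = jitter_c,
               jitter_c_core = jitter_c_core,
               mount_retention = mount_retention,
               mount_transmittance = mount_transmittance,
               paraffin_scale = paraffin_scale,
               noise_snr = noise_snr)
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec %s: %dx%d px, age %d d, %d nm, %s, seed %d\n",
    x$sample_id, x$shape[1], x$shape[2], x$age_days, x$wavelength_nm,
    x$preparation, x$seed))
  invisible(x)
}

# rasterize a disk into linear pixel indices
.disk_px <- function(cy, cx, r, rows, cols) {
  y0 <- max(1L, floor(cy - r)); y1 <- min(rows, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(cols, ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(integer(0))
  yy <- y0:y1; xx <- x0:x1
  g <- expand.grid(y = yy, x = xx)
  sel <- (g$y - cy)^2 + (g$x - cx)^2 <= r^2
  (g$x[sel] - 1L) * rows + g$y[sel]
}

#' Generate a ground-truth phantom
#'
#' Builds the per-pixel true (normalized) Mueller field of a phantom,
#' together with its class label map, exact decomposition parameter fields
#' and their tissue moments.  Deterministic in `spec` (including its
#' seed).
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `"phantom_truth"` with
#'   `mueller_map` (`rows x cols x 4 x 4`, m11-normalized),
#'   `label_map` (0 = mount/background, 1 = tissue, 2 = plaque core),
#'   `transmittance` (unpolarized transmission per pixel),
#'   `D`, `P`, `R`, `Delta` (true parameter fields),
#'   `true_moments` (data frame of tissue moments per parameter) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    rows <- spec$shape[1]; cols <- spec$shape[2]
    npx <- rows * cols
    yc <- (rows + 1) / 2; xc <- (cols + 1) / 2
    ay <- spec$tissue_axes[1] * rows; ax <- spec$tissue_axes[2] * cols
    Y <- matrix(seq_len(rows), rows, cols)
    X <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    tissue <- ((Y - yc) / ay)^2 + ((X - xc) / ax)^2 <= 1
    t_idx <- which(tissue)
    n_t <- length(t_idx)

    # class fields: 0 bg-tissue, 1 patch, 2 rim, 3 core (tissue only)
    cls <- integer(npx)
    patch_sign <- numeric(npx)

    draw_centers <- function(n) {
      # uniform inside the tissue ellipse
      u <- sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
      cbind(yc + u * ay * sin(th), xc + u * ax * cos(th))
    }

    # heterogeneity patches (symmetric, coherent sign per patch)
    pa <- pi * spec$patch_radius_px^2
    n_patch <- stats::rpois(1, spec$patch_coverage * n_t / pa)
    if (n_patch > 0) {
      ctr <- draw_centers(n_patch)
      sgn <- sample(c(-1, 1), n_patch, replace = TRUE)
      for (k in seq_len(n_patch)) {
        px <- .disk_px(ctr[k, 1], ctr[k, 2], spec$patch_radius_px, rows, cols)
        px <- px[tissue[px]]
        cls[px] <- 1L
        patch_sign[px] <- sgn[k]
      }
    }

    # plaques: rim shells first, then cores (core wins on overlap)
    lam <- default_age_schedule(spec$age_days, spec$kappa) * n_t / 1e4
    n_plq <- stats::rpois(1, lam)
    if (n_plq > 0) {
      ctr <- draw_centers(n_plq)
      for (k in seq_len(n_plq)) {
        px <- .disk_px(ctr[k, 1], ctr[k, 2],
                       spec$plaque_radius_px + spec$rim_width_px, rows, cols)
        px <- px[tissue[px]]
        cls[px] <- 2L; patch_sign[px] <- 0
      }
      for (k in seq_len(n_plq)) {
        px <- .disk_px(ctr[k, 1], ctr[k, 2], spec$plaque_radius_px, rows, cols)
        px <- px[tissue[px]]
        cls[px] <- 3L
      }
    }

    # channel retention fields (tissue pixels)
    b <- spec$background
    dB <- spec$rim_delta +
      spec$rim_delta_growth * max(0, spec$age_days - 75) / 150
    ct <- cls[t_idx]; psgn <- patch_sign[t_idx]
    a1 <- rep(b[1], n_t)
    a2 <- rep(b[2], n_t)
    cc <- rep(b[3], n_t)
    is_pa <- ct == 1L; is_ri <- ct == 2L; is_co <- ct == 3L
    a2[is_pa] <- b[2] + psgn[is_pa] * spec$patch_a2
    cc[is_pa] <- b[3] + psgn[is_pa] * spec$patch_c
    a2[is_ri] <- b[2] - 3 * dB + spec$rim_c_drop
    cc[is_ri] <- b[3] - spec$rim_c_drop
    a2[is_co] <- b[1] + b[3] - spec$core_c   # Delta-neutral core
    cc[is_co] <- spec$core_c

    a1 <- a1 + .jitter(n_t, spec$jitter_a, 0.04)
    a2 <- a2 + .jitter(n_t, spec$jitter_a, 0.04)
    cc <- cc + ifelse(is_co, .jitter(n_t, spec$jitter_c_core, 0.025),
                      .jitter(n_t, spec$jitter_c, 0.08))
    if (spec$preparation != "no_paraffin") {
      sc <- spec$paraffin_scale
      a1 <- a1 * sc; a2 <- a2 * sc; cc <- cc * sc
    }

    del <- pmax(0, spec$retardance + .jitter(n_t, 0.02, 0.06))
    th <- .jitter(n_t, 0.02, 0.06)
    Dd <- pmax(0.02, spec$diattenuation + .jitter(n_t, 0.01, 0.03))

    # enforce the Mie-core ordering m44 >= m22 pixel by pixel: the composed
    # elements are m22 = a1*(C^2 + S^2 cos(del)) and
    # m44 = c*cos(del)*sqrt(1-D^2), so lift c where jitter would break it
    if (any(is_co)) {
      c2t <- cos(2 * th)^2
      m22f <- c2t + (1 - c2t) * cos(del)
      m44f <- cos(del) * sqrt(1 - Dd^2)
      cmin <- (a1 * m22f / m44f + 0.005)[is_co]
      cc[is_co] <- pmin(pmax(cc[is_co], cmin), 0.99)
    }

    # full-image fields, mount medium outside the footprint
    A1 <- rep(spec$mount_retention, npx); A2 <- A1; CC <- A1
    DEL <- numeric(npx); TH <- numeric(npx); DD <- numeric(npx)
    A1[t_idx] <- a1; A2[t_idx] <- a2; CC[t_idx] <- cc
    DEL[t_idx] <- del; TH[t_idx] <- th; DD[t_idx] <- Dd

    # compose M = diag(1,a1,a2,c) %*% M_ret(del,th) %*% M_diat(D along H)
    cd <- cos(DEL); sd <- sin(DEL)
    c2 <- cos(2 * TH); s2 <- sin(2 * TH)
    sq <- sqrt(1 - DD^2)
    # 3x3 retarder block rows (within s1..s3)
    r11 <- c2^2 + s2^2 * cd; r12 <- c2 * s2 * (1 - cd); r13 <- -s2 * sd
    r21 <- r12;              r22 <- s2^2 + c2^2 * cd;   r23 <- c2 * sd
    r31 <- s2 * sd;          r32 <- -c2 * sd;           r33 <- cd
    el <- array(0, c(rows, cols, 4L, 4L))
    el[, , 1, 1] <- 1
    el[, , 1, 2] <- DD
    dep <- list(A1, A2, CC)
    rblk <- list(list(r11, r12, r13), list(r21, r22, r23), list(r31, r32, r33))
    for (i in 1:3) {
      # M_RD columns for rows 2..4: (R[i,1]*D, R[i,1], s*R[i,2], s*R[i,3])
      el[, , i + 1, 1] <- dep[[i]] * rblk[[i]][[1]] * DD
      el[, , i + 1, 2] <- dep[[i]] * rblk[[i]][[1]]
      el[, , i + 1, 3] <- dep[[i]] * sq * rblk[[i]][[2]]
      el[, , i + 1, 4] <- dep[[i]] * sq * rblk[[i]][[3]]
    }

    # exact decomposition fields
    Dmap <- matrix(DD, rows, cols)
    Rmap <- matrix(DEL, rows, cols)
    Delmap <- matrix(1 - (A1 + A2 + CC) / 3, rows, cols)
    Pmap <- matrix(sqrt(el[, , 2, 1]^2 + el[, , 3, 1]^2 + el[, , 4, 1]^2),
                   rows, cols)

    label <- matrix(0L, rows, cols)
    label[t_idx] <- ifelse(ct == 3L, 2L, 1L)
    trans <- matrix(spec$mount_transmittance, rows, cols)
    trans[t_idx] <- 1

    meta <- list(sample_id = spec$sample_id, age_days = spec$age_days,
                 wavelength_nm = spec$wavelength_nm,
                 preparation = spec$preparation)
    tm <- do.call(rbind, lapply(
      c("m22", "m33", "m44", "D", "P", "R", "Delta"), function(p) {
        v <- switch(p, m22 = el[, , 2, 2], m33 = el[, , 3, 3],
                    m44 = el[, , 4, 4], D = Dmap, P = Pmap, R = Rmap,
                    Delta = Delmap)
        central_moments(v[tissue], parameter_name = p, meta = meta)
      }))

    structure(list(mueller_map = el, label_map = label,
                   transmittance = trans,
                   D = Dmap, P = Pmap, R = Rmap, Delta = Delmap,
                   tissue = tissue, true_moments = tm, spec = spec,
                   meta = meta),
              class = "phantom_truth")
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "phantom_truth %s: %dx%d px, %d tissue px, %d plaque-core px\n",
    x$spec$sample_id, nrow(x$label_map), ncol(x$label_map),
    sum(x$label_map > 0), sum(x$label_map == 2L)))
  invisible(x)
}

#' Simulate the 36-state measurement of a phantom
#'
#' For every generator/analyzer state pair, computes the ideal detected
#' intensity `exposure * T * analyzer_intensity(a, M %*% S_g)` per pixel and
#' adds seeded Gaussian noise with standard deviation `signal / noise_snr`
#' (clipped at zero).
#'
#' @param gt A `"phantom_truth"`.
#' @param noise_snr Signal-to-noise ratio; use `Inf` for noiseless.
#'   Defaults to the `noise_snr` field of the phantom spec.
#' @param seed Seed for the noise stream (default: spec seed + 1).
#' @param exposure Intensity scale of the brightest beam.
#' @return An [intensity_stack()] carrying the phantom metadata.
#' @export
forward_measure <- function(gt, noise_snr = NULL, seed = NULL,
                            exposure = 10000) {
  stopifnot(inherits(gt, "phantom_truth"))
  if (is.null(noise_snr)) noise_snr <- gt$spec$noise_snr
  if (!is.numeric(noise_snr) || length(noise_snr) != 1L || noise_snr <= 0)
    stop("noise_snr must be positive (use Inf for noiseless)")
  if (is.null(seed)) seed <- gt$spec$seed + 1L
  el <- gt$mueller_map
  d <- dim(el)
  scale <- exposure * gt$transmittance
  images <- vector("list", 36L)
  names(images) <- state_pairs()
  .with_seed(seed, {
    for (g in POL_STATES) {
      sg <- stokes_of_state(g)
      # s_out_i = sum_j M[,,i,j] * sg[j], vectorized over pixels
      sout <- lapply(1:4, function(i)
        el[, , i, 1] * sg[1] + el[, , i, 2] * sg[2] +
        el[, , i, 3] * sg[3] + el[, , i, 4] * sg[4])
      for (a in POL_STATES) {
        av <- stokes_of_state(a)
        img <- 0.5 * (sout[[1]] + av[2] * sout[[2]] +
                      av[3] * sout[[3]] + av[4] * sout[[4]]) * scale
        if (is.finite(noise_snr))
          img <- img + stats::rnorm(length(img), 0, 1) * (img / noise_snr)
        images[[paste0(g, a)]] <- pmax(img, 0)
      }
    }
  })
  intensity_stack(images, meta = gt$meta)
}

#' Generate an age-series phantom cohort
#'
#' Emulates the study cohort: `replicates` phantoms at each age of `ages`
#' (default 7 ages, 75 to 225 days in 25-day steps, times 3 replicates = 21
#' samples), each with a distinct derived seed.  Deterministic in `seed`.
#'
#' @param ages Integer vector of ages in days, nonempty.
#' @param replicates Samples per age.
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param ... Passed on to [phantom_spec()] (e.g. `shape`, `wavelength_nm`,
#'   `noise_snr`).
#' @return A list with `manifest` (data frame: sample_id, age_days,
#'   wavelength_nm, preparation, seed) and `specs` (list of
#'   [phantom_spec()]s in manifest order).
#' @export
make_age_series <- function(ages = seq(75L, 225L, by = 25L), replicates = 3L,
                            seed = 1L, ...) {
  if (!length(ages)) stop("`ages` must be nonempty")
  ages <- sort(as.integer(ages))
  n <- length(ages) * replicates
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 2L, n))
  grid <- expand.grid(rep = seq_len(replicates), age = ages)
  specs <- vector("list", n)
  ids <- character(n)
  for (k in seq_len(n)) {
    ids[k] <- sprintf("a%03d_r%d", grid$age[k], grid$rep[k])
    specs[[k]] <- phantom_spec(age_days = grid$age[k], seed = seeds[k],
                               sample_id = ids[k], ...)
  }
  manifest <- data.frame(sample_id = ids, age_days = grid$age,
                         wavelength_nm = vapply(specs, `[[`, 0L, "wavelength_nm"),
                         preparation = vapply(specs, `[[`, "", "preparation"),
                         seed = seeds, stringsAsFactors = FALSE)
  list(manifest = manifest, specs = specs)
}
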