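# First-to-fourth central moments of parameter maps, aggregation across
# samples by age group, and linear/exponential trend fits against age.

#' Population central moments of a parameter map
#'
#' Computes, in population (1/N) form,
#' * mean `mu = sum(x) / N`,
#' * standard deviation `sigma = sqrt(sum((x - mu)^2) / N)`,
#' * skewness `sum((x - mu)^3) / (N * sigma^3)`,
#' * kurtosis `sum((x - mu)^4) / (N * sigma^4)` (non-excess: Gaussian -> 3).
#'
#' @param values Numeric vector of map values over the region of interest;
#'   masked/sentinel entries must already be removed.
#' @param parameter_name Name of the summarized parameter (e.g. `"m44"`,
#'   `"Delta"`).
#' @param meta Optional sample metadata list carried into the summary
#'   (fields such as `sample_id`, `age_days`, `wavelength_nm`,
#'   `preparation`).
#' @return One-row data frame of class `"moment_summary"` with columns
#'   `parameter`, `mean`, `std`, `skewness`, `kurtosis`, `n_pixels` and any
#'   metadata fields.  With zero spread (`sigma = 0`), skewness and kurtosis
#'   are `NA` (undefined), not numbers.
#' @export
central_moments <- function(values, parameter_name = "value", meta = list()) {
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (any(!is.finite(values)))
    stop("`values` contains non-finite entries; remove masked pixels first")
  n <- length(values)
  if (n < 2L) stop("at least 2 values are required")
  mu <- mean(values)
  ctr <- values - mu
  sigma <- sqrt(mean(ctr^2))
  if (sigma > 0) {
    skew <- mean(ctr^3) / sigma^3
    kurt <- mean(ctr^4) / sigma^4
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  out <- data.frame(parameter = parameter_name, mean = mu, std = sigma,
                    skewness = skew, kurtosis = kurt, n_pixels = n,
                    stringsAsFactors = FALSE)
  for (f in c("sample_id", "age_days", "wavelength_nm", "preparation"))
    if (!is.null(meta[[f]])) out[[f]] <- meta[[f]]
  class(out) <- c("moment_summary", class(out))
  out
}

#' Moments of every requested map of a sample
#'
#' Convenience layer over [central_moments()]: summarizes the masked-in
#' pixels of selected Mueller elements and decomposition parameters of one
#' sample.
#'
#' @param img Normalized `"mueller_image"`.
#' @param maps Optional `"decomposition_maps"` for the same sample.
#' @param parameters Character vector drawn from
#'   `c("m22", "m33", "m44", "D", "P", "R", "Delta")`.
#' @param roi Optional logical matrix restricting the summarized pixels
#'   (combined with the validity mask).
#' @return Data frame with one `moment_summary` row per parameter.
#' @export
sample_moments <- function(img, maps = NULL,
                           parameters = c("m22", "m44", "Delta"),
                           roi = NULL) {
  stopifnot(inherits(img, "mueller_image"))
  keep <- img$mask
  if (!is.null(roi)) keep <- keep & roi
  if (!any(keep)) stop("empty region of interest; no pixels to summarize")
  rows <- lapply(parameters, function(p) {
    v <- switch(p,
      m22 = mm_element(img, 2, 2),
      m33 = mm_element(img, 3, 3),
      m44 = mm_element(img, 4, 4),
      D = , P = , R = , Delta = {
        if (is.null(maps))
          stop("parameter ", p, " requires decomposition maps")
        maps[[p]]
      },
      stop("unknown parameter: ", p)
    )
    central_moments(v[keep & is.finite(v)], parameter_name = p,
                    meta = img$meta)
  })
  do.call(rbind, rows)
}

#' Aggregate moment summaries by age group
#'
#' Groups per-sample summaries of a single parameter by `age_days`; within
#' each group reports the arithmetic mean of each moment across samples and
#' the across-sample standard deviation as its error bar, then attaches
#' trend fits: by convention linear fits for mean and standard deviation,
#' exponential fits for skewness and kurtosis (configurable).
#'
#' @param summaries Data frame of `moment_summary` rows sharing one
#'   `parameter` (and wavelength, if present).
#' @param fit_models Named character vector choosing `"linear"` or
#'   `"exponential"` per moment.
#' @param fit_on `"group_means"` (default) fits the per-age group means;
#'   `"samples"` fits all individual sample values.
#' @return An object of class `"group_trend"`: `parameter`, `ages`,
#'   `table` (per-age mean and sd of each moment) and `fits` (a
#'   [fit_linear()]/[fit_exponential()] result per moment).
#' @export
moments_by_group <- function(summaries,
                             fit_models = c(mean = "linear", std = "linear",
                                            skewness = "exponential",
                                            kurtosis = "linear"),
                             fit_on = c("group_means", "samples")) {
  fit_on <- match.arg(fit_on)
  if (is.null(summaries) || nrow(summaries) == 0L)
    stop("no summaries to aggregate")
  if (length(unique(summaries$parameter)) != 1L)
    stop("summaries mix parameters: ",
         paste(unique(summaries$parameter), collapse = ", "))
  if (!is.null(summaries$wavelength_nm) &&
      length(unique(summaries$wavelength_nm)) != 1L)
    stop("summaries mix wavelengths")
  if (is.null(summaries$age_days)) stop("summaries carry no age_days")

  ages <- sort(unique(summaries$age_days))
  moments <- c("mean", "std", "skewness", "kurtosis")
  tab <- data.frame(age_days = ages)
  for (mo in moments) {
    tab[[mo]] <- vapply(ages, function(a)
      mean(summaries[[mo]][summaries$age_days == a], na.rm = TRUE), 0)
    tab[[paste0(mo, "_sd")]] <- vapply(ages, function(a) {
      v <- summaries[[mo]][summaries$age_days == a]
      if (length(v) > 1L) stats::sd(v, na.rm = TRUE) else 0
    }, 0)
  }

  fits <- lapply(moments, function(mo) {
    if (fit_on == "group_means") { x <- tab$age_days; y <- tab[[mo]] }
    else { x <- summaries$age_days; y <- summaries[[mo]] }
    ok <- is.finite(x) & is.finite(y)
    model <- fit_models[[mo]]
    tryCatch(
      if (model == "exponential") fit_exponential(x[ok], y[ok])
      else fit_linear(x[ok], y[ok]),
      error = function(e) list(model = model, converged = FALSE,
                               error = conditionMessage(e)))
  })
  names(fits) <- moments

  structure(list(parameter = summaries$parameter[1], ages = ages,
                 table = tab, fits = fits),
            class = "group_trend")
}

#' @export
print.group_trend <- function(x, ...) {
  cat("group_trend for", x$parameter, "over ages",
      paste(x$ages, collapse = ", "), "\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Ordinary least-squares line fit
#'
#' @param x,y Numeric vectors (e.g. age in days and a moment value).
#' @return List of class `"mm_fit"`: `model = "linear"`, `params`
#'   (`slope`, `intercept`), `residual_norm`, `converged`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(unique(x)) < 2L) stop("need at least 2 distinct x values")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  structure(list(model = "linear",
                 params = c(slope = unname(cf[2]), intercept = unname(cf[1])),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 converged = TRUE),
            class = "mm_fit")
}

#' Exponential trend fit with offset
#'
#' Nonlinear least squares for `y = alpha * exp(beta * x) + offset`
#' (Levenberg-Marquardt).  The three-parameter form is used because the
#' fitted moments (e.g. skewness) can be negative, which a two-parameter
#' exponential cannot reach.  Initialized from a log-linear regression on
#' the offset-shifted response.  With effectively constant `y` the model is
#' degenerate; the offset-dominated best iterate is returned with
#' `converged = FALSE` rather than a silent fallback.
#'
#' @param x,y Numeric vectors; at least 4 points (3 parameters).
#' @return List of class `"mm_fit"`: `model = "exponential"`, `params`
#'   (`alpha`, `beta`, `offset`), `residual_norm`, `converged`.
#' @export
fit_exponential <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 points for the 3-parameter fit")

  yr <- diff(range(y))
  if (yr <= max(1e-12, 1e-10 * max(abs(y), 1))) {
    # constant response: beta -> 0 branch, offset-dominated
    return(structure(list(model = "exponential",
                          params = c(alpha = 0, beta = 0,
                                     offset = mean(y)),
                          residual_norm = sqrt(sum((y - mean(y))^2)),
                          converged = FALSE),
                     class = "mm_fit"))
  }

  # start values from a log-linear regression on the shifted response,
  # trying both orientations (growth and decay)
  starts <- list()
  for (sgn in c(1, -1)) {
    ys <- sgn * y
    shift <- min(ys) - 0.05 * yr
    ll <- stats::lm(log(ys - shift) ~ x)
    starts[[length(starts) + 1L]] <-
      list(alpha = sgn * exp(unname(stats::coef(ll)[1])),
           beta = unname(stats::coef(ll)[2]),
           offset = sgn * shift)
  }
  starts[[length(starts) + 1L]] <-
    list(alpha = yr, beta = 1 / diff(range(x)), offset = min(y))

  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ alpha * exp(beta * x) + offset,
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) next
    rn <- sqrt(sum(stats::residuals(f)^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = f, rn = rn)
  }
  if (is.null(best))
    return(structure(list(model = "exponential",
                          params = c(alpha = NA_real_, beta = NA_real_,
                                     offset = NA_real_),
                          residual_norm = NA_real_, converged = FALSE),
                     class = "mm_fit"))
  cf <- stats::coef(best$fit)
  structure(list(model = "exponential",
                 params = c(alpha = unname(cf["alpha"]),
                            beta = unname(cf["beta"]),
                            offset = unname(cf["offset"])),
                 residual_norm = best$rn,
                 converged = isTRUE(best$fit$convInfo$isConv)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): %s; residual norm %.4g\n", x$model,
              if (isTRUE(x$converged)) "converged" else "not converged",
              paste(names(x$params), signif(x$params, 5),
                    sep = " = ", collapse = ", "),
              x$residual_norm))
  invisible(x)
}

#' Tabular report of group trends
#'
#' Renders one block per parameter with rows Mean/Std/Skew/Kurt and one
#' column per age group (ascending), the layout used for summary tables of
#' polarimetric parameters across sample age.
#'
#' @param trends List of `"group_trend"` objects.
#' @return Data frame with columns `parameter`, `moment` and one column per
#'   age (named `age_<days>`).  Write with [write_trend_table()]; a
#'   plain-text rendering is available via `format_trend_table()`.
#' @export
trend_table <- function(trends) {
  if (inherits(trends, "group_trend")) trends <- list(trends)
  rows <- lapply(trends, function(tr) {
    lab <- c(mean = "Mean", std = "Std", skewness = "Skew",
             kurtosis = "Kurt")
    blk <- data.frame(parameter = tr$parameter, moment = unname(lab),
                      stringsAsFactors = FALSE)
    ord <- order(tr$table$age_days)
    for (k in seq_along(ord)) {
      a <- tr$table$age_days[ord[k]]
      blk[[paste0("age_", a)]] <-
        vapply(names(lab), function(mo) tr$table[[mo]][ord[k]], 0)
    }
    blk
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname trend_table
#' @param table A data frame produced by [trend_table()].
#' @param path File path for the CSV rendering.
#' @export
write_trend_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trend_table
#' @export
read_trend_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname trend_table
#' @export
format_trend_table <- function(table) {
  agecols <- grep("^age_", names(table), value = TRUE)
  hdr <- sprintf("%-10s %-5s %s", "parameter", "",
                 paste(sprintf("%9s", sub("age_", "", agecols)),
                       collapse = " "))
  body <- apply(table, 1, function(r)
    sprintf("%-10s %-5s %s", r[["parameter"]], r[["moment"]],
            paste(sprintf("%9.3f", as.numeric(r[agecols])), collapse = " ")))
  paste(c(hdr, body), collapse = "\n")
}
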