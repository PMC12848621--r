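# End-to-end orchestration: configuration, per-sample processing chain
# (reconstruct -> normalize -> mask -> decompose -> moments), cohort
# aggregation, trend fits and report files.

#' Assemble a pipeline run configuration
#'
#' Either `manifest_dir` (a directory of measured/simulated samples, one
#' subdirectory per sample as written by [write_stack()] plus a
#' `manifest.csv`) or `phantom` (an in-memory synthetic cohort description)
#' must be supplied.
#'
#' @param manifest_dir Directory with sample subdirectories and
#'   `manifest.csv` (columns `sample_id`, `age_days`, ...).
#' @param phantom List of arguments for [make_age_series()] (e.g. `ages`,
#'   `replicates`, `shape`, `noise_snr`, `wavelength_nm`).
#' @param parameters Parameter maps to analyze, subset of
#'   `c("m22", "m33", "m44", "D", "P", "R", "Delta")`.
#' @param roi Region-of-interest rule, `list(method=, param=)` as in
#'   [tissue_mask()].
#' @param floor Normalization floor for [normalize_by_m11()].
#' @param eps Decomposition tolerance, see [decompose_mueller()].
#' @param fit_models,fit_on Trend-fit choices, see [moments_by_group()].
#' @param out_dir Output directory for reports (`NULL` = no files).
#' @param seed Master seed for any simulation randomness.
#' @param write_maps Also write per-sample parameter-map TIFFs.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(manifest_dir = NULL, phantom = NULL,
                       parameters = c("m22", "m44", "Delta"),
                       roi = list(method = "percentile", param = 50),
                       floor = 0.01, eps = 1e-6,
                       fit_models = c(mean = "linear", std = "linear",
                                      skewness = "exponential",
                                      kurtosis = "linear"),
                       fit_on = "group_means",
                       out_dir = NULL, seed = 1L, write_maps = FALSE) {
  if (is.null(manifest_dir) && is.null(phantom))
    stop("supply either `manifest_dir` or `phantom`")
  if (!length(parameters)) stop("`parameters` must be nonempty")
  bad <- setdiff(parameters, c("m22", "m33", "m44", "D", "P", "R", "Delta"))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  structure(list(manifest_dir = manifest_dir, phantom = phantom,
                 parameters = parameters, roi = roi, floor = floor,
                 eps = eps, fit_models = fit_models, fit_on = fit_on,
                 out_dir = out_dir, seed = as.integer(seed),
                 write_maps = write_maps),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$fit_models)) y$fit_models <- unlist(y$fit_models)
  do.call(run_config, y)
}

#' Process one intensity stack through the analysis chain
#'
#' Reconstruction, m11 normalization, region-of-interest masking,
#' pixelwise polar decomposition and moment summaries.
#'
#' @param stack An [intensity_stack()].
#' @param config A [run_config()].
#' @return List with `moments` (data frame), `img` (normalized Mueller
#'   image), `maps` (decomposition maps) and `roi` (logical matrix).
#' @export
process_sample <- function(stack, config) {
  raw <- reconstruct_mueller(stack)
  roi <- tissue_mask(raw, method = config$roi$method,
                     param = config$roi$param)
  img <- normalize_by_m11(raw, floor = config$floor)
  needs_decomp <- any(config$parameters %in% c("D", "P", "R", "Delta"))
  maps <- if (needs_decomp) decompose_image(img, eps = config$eps) else NULL
  mom <- sample_moments(img, maps = maps, parameters = config$parameters,
                        roi = roi)
  list(moments = mom, img = img, maps = maps, roi = roi)
}

#' Write a simulated cohort to disk
#'
#' Generates the configured phantom cohort and writes, per sample, the 36
#' intensity TIFFs with `meta.yaml`, the ground-truth moment table, plus a
#' top-level `manifest.csv`.
#'
#' @param config A [run_config()] with a `phantom` entry.
#' @param dir Output directory.
#' @return The manifest data frame, invisibly.
#' @export
simulate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "run_config"), !is.null(config$phantom))
  series <- do.call(make_age_series,
                    c(config$phantom, list(seed = config$seed)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth_rows <- list()
  for (k in seq_len(nrow(series$manifest))) {
    gt <- generate_phantom(series$specs[[k]])
    stack <- forward_measure(gt)
    write_stack(stack, file.path(dir, series$manifest$sample_id[k]))
    truth_rows[[k]] <- gt$true_moments
  }
  utils::write.csv(series$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  write_moments_csv(do.call(rbind, truth_rows),
                    file.path(dir, "truth_moments.csv"))
  invisible(series$manifest)
}

#' Run the full analysis pipeline
#'
#' Executes reconstruct, normalize, mask, decompose, moments, group trends
#' and reports for every sample of the configured cohort.  Samples failing
#' input validation are skipped with a logged reason; an empty result set is
#' an error.  Deterministic for a fixed configuration (including seed).
#'
#' @param config A [run_config()] (or path to its YAML file).
#' @return List of class `"pipeline_result"`: `moments` (per-sample rows),
#'   `trends` (one `"group_trend"` per parameter), `table` (trend table),
#'   `log` (processed/skipped counts and reasons).  When `out_dir` is set,
#'   writes `moments.csv`, `trends.csv`, `trend_table.csv`,
#'   `trend_table.txt` and `run_log.yaml` there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$manifest_dir)) {
    man <- utils::read.csv(file.path(config$manifest_dir, "manifest.csv"),
                           stringsAsFactors = FALSE)
    get_stack <- function(k) read_stack(file.path(config$manifest_dir,
                                                  man$sample_id[k]))
  } else {
    series <- do.call(make_age_series,
                      c(config$phantom, list(seed = config$seed)))
    man <- series$manifest
    get_stack <- function(k) forward_measure(generate_phantom(series$specs[[k]]))
  }

  moments <- list(); skipped <- list()
  for (k in seq_len(nrow(man))) {
    res <- tryCatch({
      out <- process_sample(get_stack(k), config)
      if (!is.null(config$out_dir) && config$write_maps &&
          !is.null(out$maps)) {
        dir.create(file.path(config$out_dir, "maps"), recursive = TRUE,
                   showWarnings = FALSE)
        write_maps(out$maps, file.path(config$out_dir, "maps",
                                       man$sample_id[k]))
      }
      out$moments
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[man$sample_id[k]]] <- conditionMessage(res)
      message("skipping sample ", man$sample_id[k], ": ",
              conditionMessage(res))
    } else {
      moments[[k]] <- res
    }
  }
  moments <- do.call(rbind, moments)
  if (is.null(moments) || nrow(moments) == 0L)
    stop("no sample processed successfully (",
         length(skipped), " skipped)")

  trends <- lapply(config$parameters, function(p)
    moments_by_group(moments[moments$parameter == p, ],
                     fit_models = config$fit_models,
                     fit_on = config$fit_on))
  names(trends) <- config$parameters
  tab <- trend_table(trends)

  log <- list(package_version = as.character(utils::packageVersion("mmpolar")),
              n_samples = nrow(man), n_processed = nrow(man) - length(skipped),
              n_skipped = length(skipped), skipped = skipped,
              parameters = config$parameters, seed = config$seed,
              roi = config$roi, floor = config$floor, fit_on = config$fit_on)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_moments_csv(moments, file.path(config$out_dir, "moments.csv"))
    write_trends_csv(trends, file.path(config$out_dir, "trends.csv"))
    write_trend_table(tab, file.path(config$out_dir, "trend_table.csv"))
    writeLines(format_trend_table(tab),
               file.path(config$out_dir, "trend_table.txt"))
    yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))
  }

  structure(list(moments = moments, trends = trends, table = tab, log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d/%d samples, parameters %s\n",
              x$log$n_processed, x$log$n_samples,
              paste(x$log$parameters, collapse = ", ")))
  cat(format_trend_table(x$table), "\n")
  invisible(x)
}
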