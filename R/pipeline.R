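# End-to-end orchestration: segment colors -> temperature join -> models.
# Every stochastic stage is governed by the single `seed` in the config, so
# a rerun of the same config is bit-identical. Retention is accounted
# stage by stage: input = modeled + sum of per-stage drops.

#' Default pipeline configuration
#'
#' @param seed master seed.
#' @param n_records records in the simulated bundle.
#' @param ... overrides for [synth_config()] fields.
#' @return a config list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, n_records = 2000L, ...) {
  list(simulate = TRUE, seed = as.integer(seed),
       synth = list(n_records = n_records, seed = as.integer(seed),
                    unclear_frac = 0.1, missing_temp_frac = 0.02, ...),
       k = 4, ring_width = 20L, level = 0.95)
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- default_pipeline_config()
  for (nm in setdiff(names(defaults), names(config))) {
    config[[nm]] <- defaults[[nm]]
  }
  config
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain a bundle -- either simulated from `config$synth` or
#' read from `config$bundle_dir`; (2) extract dominant colors and
#' green/brown/unclear labels from the segment images, excluding unclear
#' segments; (3) attach reconstructed hourly temperatures, dropping
#' records with missing daily entries; (4) fit the three logistic-
#' regression variants, the three cyclic-GAM variants, and the
#' background-matching OLS, with AIC comparison within each family;
#' (5) assemble prediction curves (seasonal curves at the 10th/50th/90th
#' latitude percentiles; temperature curves per season) and the retention
#' log.
#'
#' @param config a config list, or the path to a YAML file. Recognized
#'   fields: `simulate` (logical), `synth` (a [synth_config()] field
#'   list), `bundle_dir` (when `simulate` is false), `k`, `ring_width`,
#'   `level`.
#' @param out_dir optional directory; when given, result tables are
#'   written as CSV and the model report + retention log as JSON.
#' @return a list of class `anole_report`: `retention`, `colors`,
#'   `records`, `glm` (fits + comparison), `gam`, `background`, `curves`,
#'   `config`, plus `truth`/`meta` when simulating.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- load_pipeline_config(config)

  # -- stage 1: inputs -------------------------------------------------
  if (isTRUE(config$simulate)) {
    bundle <- gen_synth_bundle(do.call(synth_config, config$synth))
  } else {
    if (is.null(config$bundle_dir)) {
      stop("pipeline stage input: either simulate: true or bundle_dir ",
           "must be given", call. = FALSE)
    }
    bundle <- read_synth_bundle(config$bundle_dir)
  }
  n_input <- nrow(bundle$records)
  stage_log("input", "n=%d", n_input)

  # -- stage 2: segment colors ----------------------------------------
  colors <- process_segments(bundle$images, k = config$k,
                             ring_width = config$ring_width,
                             seed = config$seed)
  records <- merge(bundle$records, colors, by = "id", sort = FALSE)
  records <- records[order(records$id), ]
  n_unclear <- sum(records$excluded_flag)
  kept <- records[!records$excluded_flag, , drop = FALSE]
  stage_log("color", "labeled=%d unclear_excluded=%d", nrow(records),
            n_unclear)

  # -- stage 3: hourly temperatures -----------------------------------
  kept <- attach_temperatures(kept, bundle$daily, bundle$grid)
  drop_log <- attr(kept, "drop_log")
  stage_log("temperature", "attached=%d dropped_missing_daily=%d",
            drop_log$n_retained, drop_log$n_dropped_missing_daily)

  # -- stage 4: models -------------------------------------------------
  glm_fits <- lapply(c("temp_only", "temp_plus_season",
                       "temp_by_season_interaction"),
                     function(v) fit_logistic(kept, v))
  glm_cmp <- aic_compare(glm_fits)
  gam_fits <- lapply(c("week_only", "week_plus_lat",
                       "week_by_lat_interaction"),
                     function(v) fit_cyclic_gam(kept, v))
  gam_cmp <- aic_compare(gam_fits)
  background <- fit_background_lm(kept)
  stage_log("models", "glm_best=%s gam_best=%s", glm_cmp$best, gam_cmp$best)

  # -- stage 5: curves + retention ------------------------------------
  gam_int <- gam_fits[[3L]]
  lat_q <- stats::quantile(kept$latitude, c(0.1, 0.5, 0.9), names = FALSE)
  grid_season <- expand.grid(week = seq(0, 52, by = 0.5), latitude = lat_q)
  curves_season <- cbind(grid_season,
                         predict_with_ci(gam_int, grid_season,
                                         level = config$level))
  glm_int <- glm_fits[[3L]]
  grid_temp <- expand.grid(
    hourly_temp = seq(min(kept$hourly_temp), max(kept$hourly_temp),
                      length.out = 60),
    season = factor(SEASON_LEVELS, levels = SEASON_LEVELS))
  curves_temp <- cbind(grid_temp,
                       predict_with_ci(glm_int, grid_temp,
                                       level = config$level))

  retention <- list(input = n_input,
                    color_labeled = nrow(records),
                    unclear_excluded = n_unclear,
                    temperature_dropped = drop_log$n_dropped_missing_daily,
                    modeled = nrow(kept))

  report <- structure(list(
    retention = retention,
    colors = colors,
    records = kept,
    glm = glm_cmp,
    gam = gam_cmp,
    background = background,
    curves = list(seasonal = curves_season, temperature = curves_temp,
                  latitude_percentiles = lat_q),
    truth = bundle$truth,
    meta = bundle$meta,
    config = config
  ), class = "anole_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.anole_report <- function(x, ...) {
  r <- x$retention
  cat(sprintf(paste0(
    "<anole_report: %d records in, %d modeled\n",
    "  unclear excluded: %d; missing-temperature drops: %d\n",
    "  GLM best: %s (delta AIC %.1f); GAM best: %s (delta AIC %.1f)\n",
    "  background matching: slope %.3f, R^2 %.3f>\n"),
    r$input, r$modeled, r$unclear_excluded, r$temperature_dropped,
    x$glm$best, x$glm$delta_aic, x$gam$best, x$gam$delta_aic,
    x$background$slope, x$background$r_squared))
  invisible(x)
}

fit_summary <- function(f) {
  list(model = f$model_name,
       coefficients = as.list(f$coefficients),
       se = as.list(f$se),
       deviance = f$deviance,
       null_deviance = f$null_deviance,
       effective_df = f$effective_df,
       aic = f$aic,
       deviance_explained = f$deviance_explained,
       adj_pseudo_r2_approx = f$adj_pseudo_r2,
       season_slopes = f$season_slopes)
}

#' Write a pipeline report to disk
#'
#' CSVs (`colors.csv`, `records_modeled.csv`, `curves_seasonal.csv`,
#' `curves_temperature.csv`) plus `model_report.json` and
#' `retention_log.json`. No timestamps are written, so identical runs
#' produce identical files.
#'
#' @param report an `anole_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$colors, file.path(out_dir, "colors.csv"),
                   row.names = FALSE)
  utils::write.csv(report$records, file.path(out_dir, "records_modeled.csv"),
                   row.names = FALSE)
  utils::write.csv(report$curves$seasonal,
                   file.path(out_dir, "curves_seasonal.csv"),
                   row.names = FALSE)
  utils::write.csv(report$curves$temperature,
                   file.path(out_dir, "curves_temperature.csv"),
                   row.names = FALSE)
  model_report <- list(
    glm = list(table = report$glm$table, best = report$glm$best,
               delta_aic = report$glm$delta_aic,
               fits = lapply(report$glm$fits, fit_summary)),
    gam = list(table = report$gam$table, best = report$gam$best,
               delta_aic = report$gam$delta_aic,
               fits = lapply(report$gam$fits, fit_summary)),
    background = report$background)
  jsonlite::write_json(model_report, file.path(out_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(report$retention,
                       file.path(out_dir, "retention_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Validate a pipeline report against generator ground truth
#'
#' @param report an `anole_report` from a simulated run (or any report
#'   whose records can be matched to `truth` by id).
#' @param truth a truth table from [gen_observation_table()]; defaults to
#'   the one carried by the report.
#' @return a list: `label_accuracy` (fraction of modeled records whose
#'   pipeline label equals the planted label), `temp_rmse` (reconstructed
#'   vs true hourly temperature), `coefficient_errors` (interaction-GLM
#'   per-season slopes minus the planted slopes), and `n_compared`.
#' @export
validate_against_truth <- function(report, truth = report$truth) {
  if (is.null(truth)) stop("no truth table available", call. = FALSE)
  m <- match(report$records$id, truth$record_id)
  if (anyNA(m)) stop("record ids missing from the truth table", call. = FALSE)
  tr <- truth[m, , drop = FALSE]
  acc <- mean(report$records$label == tr$true_label)
  rmse <- sqrt(mean((report$records$hourly_temp - tr$true_hourly_temp)^2))
  coef_err <- NULL
  syn <- report$config$synth
  if (!is.null(syn)) {
    planted <- c(nonbreeding = syn$beta_temp_nonbreeding %||% 0.12,
                 breeding = syn$beta_temp_breeding %||% 0)
    sl <- report$glm$fits[[3L]]$season_slopes
    coef_err <- data.frame(
      season = sl$season,
      planted = unname(planted[sl$season]),
      estimate = sl$slope,
      error = sl$slope - unname(planted[sl$season]))
  }
  list(label_accuracy = acc, temp_rmse = rmse,
       coefficient_errors = coef_err, n_compared = nrow(report$records))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
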