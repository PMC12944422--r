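#' Write a run manifest
#'
#' JSON record of everything needed to reproduce a run: package version,
#' seeds, configuration, and MD5 hashes of input/output files.
#'
#' @param path Output JSON path.
#' @param ... Named fields to record.
#' @return `path`, invisibly.
#' @keywords internal
.write_manifest <- function(path, ...) {
  fields <- list(...)
  fields$package <- "thermocal"
  fields$version <- as.character(utils::packageVersion("thermocal"))
  fields$r_version <- as.character(getRversion())
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.file_hashes <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(as.list(unname(h)), basename(paths))
}

#' Simulate a study and write it to disk
#'
#' Generates a synthetic paired-device study and writes the measurement CSV
#' plus a JSON manifest recording the full generator configuration.
#'
#' @param config A [study_config()]; default [default_study_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with `measurements` (path) and `manifest` (path).
#' @export
run_simulate <- function(config = default_study_config(), outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- generate_study(config)
  csv <- file.path(outdir, "measurements.csv")
  write_measurements(tab, csv)
  cfg <- unclass(config)
  cfg$pop_mean <- as.list(cfg$pop_mean)
  cfg$ref_noise_sd <- as.list(cfg$ref_noise_sd)
  cfg$test_noise_sd <- as.list(cfg$test_noise_sd)
  cfg$bias_intercept <- as.list(cfg$bias_intercept)
  manifest <- file.path(outdir, "simulate_manifest.json")
  .write_manifest(manifest, stage = "simulate", config = cfg,
                  n_records = nrow(tab), outputs = .file_hashes(csv))
  message("wrote ", nrow(tab), " records to ", csv)
  invisible(list(measurements = csv, manifest = manifest))
}

.as_measurements <- function(input, schema = measurement_schema()) {
  if (is.data.frame(input)) return(input)
  read_measurements(input, schema)
}

#' Agreement analysis report
#'
#' Runs the full agreement analysis on a measurement table (or CSV path) and
#' writes a per-round summary table (rows: statistics; columns: rounds), a
#' per-unit Bland-Altman points CSV with bias/LoA reference values, and a
#' manifest.
#'
#' @param input Measurement tibble or CSV path.
#' @param outdir Output directory.
#' @param level Analysis level, see [bland_altman()].
#' @return Invisibly, list of output paths plus the summary tibble.
#' @export
run_agreement <- function(input, outdir = ".",
                          level = c("participant_means", "replicates")) {
  level <- match.arg(level)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- .as_measurements(input)
  summary_long <- agreement_summary(tab, level = level)
  wide <- tidyr::pivot_wider(summary_long, names_from = "round",
                             values_from = "value")
  summary_csv <- file.path(outdir, "agreement_summary.csv")
  readr::write_csv(wide, summary_csv, progress = FALSE)
  pairs <- pair_replicates(tab)
  pts <- purrr::map_dfr(sort(unique(tab$round)), function(r) {
    ba <- bland_altman(pairs, round = r, level = level)
    dplyr::mutate(ba$points, round = r, bias = ba$bias,
                  loa_lower = ba$loa_lower, loa_upper = ba$loa_upper)
  })
  points_csv <- file.path(outdir, "ba_points.csv")
  readr::write_csv(pts, points_csv, progress = FALSE)
  manifest <- file.path(outdir, "agreement_manifest.json")
  .write_manifest(manifest, stage = "agree", level = level,
                  input_hash = if (is.character(input)) .file_hashes(input) else "in-memory",
                  outputs = .file_hashes(c(summary_csv, points_csv)))
  message("agreement summary for rounds: ",
          paste(unique(summary_long$round), collapse = ", "))
  invisible(list(summary = summary_csv, points = points_csv,
                 manifest = manifest, table = wide))
}

#' Calibration suite report
#'
#' Runs the ten-model calibration suite (plus raw reference row) with
#' participant-grouped cross-validation on the pooled rounds, and writes the
#' metrics table, per-model out-of-fold predictions, and a manifest. With
#' `grid = TRUE`, tunable models are first grid-searched on the same folds.
#'
#' @param input Measurement tibble or CSV path.
#' @param outdir Output directory.
#' @param specs Calibrator specifications; default all ten.
#' @param k Number of grouped folds.
#' @param fold_seed,model_seed Seeds for fold shuffling and stochastic fits.
#' @param grid Run the hyperparameter grid search before the final suite.
#' @return Invisibly, list of output paths plus the metrics tibble.
#' @export
run_calibration <- function(input, outdir = ".",
                            specs = default_calibrator_specs(model_seed),
                            k = 5L, fold_seed = 0L, model_seed = 0L,
                            grid = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- .as_measurements(input)
  pairs <- pair_replicates(tab)
  folds <- group_kfold(pairs$participant_id, k = k, seed = fold_seed)
  if (grid) {
    specs <- lapply(specs, function(spec) {
      g <- default_grid(spec$model)
      if (nrow(g) <= 1L) return(spec)
      grid_search(pairs, spec$model, folds, grid = g, seed = model_seed)$best_spec
    })
  }
  suite <- run_calibration_suite(pairs, specs, folds)
  metrics_csv <- file.path(outdir, "calibration_metrics.csv")
  readr::write_csv(tibble::as_tibble(suite), metrics_csv, progress = FALSE)
  preds <- attr(suite, "predictions")
  preds_csv <- file.path(outdir, "oof_predictions.csv")
  purrr::imap_dfr(preds, function(p, nm) dplyr::mutate(p, model = nm)) |>
    readr::write_csv(preds_csv, progress = FALSE)
  hyper <- lapply(specs, function(s) c(list(model = s$model, seed = s$seed),
                                       s$params))
  manifest <- file.path(outdir, "calibration_manifest.json")
  .write_manifest(manifest, stage = "calibrate", k = k,
                  fold_seed = fold_seed, model_seed = model_seed,
                  grid_search = grid, specs = hyper,
                  input_hash = if (is.character(input)) .file_hashes(input) else "in-memory",
                  outputs = .file_hashes(c(metrics_csv, preds_csv)))
  message("calibration suite: ", nrow(suite), " model rows written")
  invisible(list(metrics = metrics_csv, predictions = preds_csv,
                 manifest = manifest, table = suite))
}
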