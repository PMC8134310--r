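# One-call drivers tying simulation and evaluation into reproducible runs
# with manifests, plus the JSON/text report writers. A thin command-line
# wrapper over these functions ships in inst/scripts/biopsynav.

#' Simulate an experiment dataset to disk
#'
#' Generates a full synthetic experiment ([generate_experiment()]) and
#' writes it as a dataset directory with a manifest.
#'
#' @param config An [experiment_config()], or the path of a YAML config
#'   file ([read_config()]).
#' @param out_dir Output dataset directory.
#' @param seed Optional integer overriding the config's seed.
#' @return The generated `"biopsy_experiment"`, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  exp <- generate_experiment(config)
  write_experiment(exp, out_dir)
  write_manifest(out_dir, seed = config$seed,
                 extra = list(stage = "simulate",
                              n_resampled = exp$n_resampled))
  invisible(exp)
}

#' Evaluate a dataset directory and write the accuracy report
#'
#' Reads a dataset directory ([read_experiment()]), runs the full accuracy
#' analysis ([evaluate_experiment()]), and writes `errors.csv` (every error
#' record, exclusions flagged and retained), `summary.json`, rendered
#' `tables.txt`, `registrations.json` (the recorded frame-registration
#' transforms) and a manifest into `out_dir`.
#'
#' @param dataset_dir Dataset directory produced by [run_simulate()] (or
#'   assembled from real pick tables in the same dialect).
#' @param out_dir Output directory for the report files.
#' @param conf_level Confidence level for summary CIs.
#' @return The `"biopsy_evaluation"`, invisibly.
#' @export
run_evaluate <- function(dataset_dir, out_dir, conf_level = 0.95) {
  exp <- read_experiment(dataset_dir)
  ev <- evaluate_experiment(exp, conf_level = conf_level)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ev$records, file.path(out_dir, "errors.csv"),
                   row.names = FALSE)
  jsonlite::write_json(evaluation_summary(ev),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(utils::capture.output(print(ev)), file.path(out_dir, "tables.txt"))
  regs <- lapply(ev$registrations, function(r)
    list(transform = rt_serialize(r$transform), fre_mm = r$fre))
  jsonlite::write_json(regs, file.path(out_dir, "registrations.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, seed = exp$config$seed,
                 extra = list(stage = "evaluate",
                              excluded_needles = ev$exclusion_log$needle_id))
  invisible(ev)
}

#' Flatten an evaluation into a JSON-ready summary list
#'
#' @param ev A `"biopsy_evaluation"`.
#' @return Named list with per-metric summary statistics, interobserver
#'   variances, ground-truth pick variability, sample accounting and the
#'   exclusion log.
#' @export
evaluation_summary <- function(ev) {
  stopifnot(inherits(ev, "biopsy_evaluation"))
  s <- lapply(ev$summaries, function(x)
    x[c("n", "mean", "sd", "min", "max", "ci_low", "ci_high", "units")])
  list(metrics = s,
       interobserver_variance_mm2 = as.list(ev$interobserver),
       ground_truth_variability = ev$gt_stats[c("n_needles", "mean", "sd",
                                                "min", "max")],
       n_records = nrow(ev$records),
       n_kept = nrow(ev$kept),
       n_excluded = nrow(ev$excluded),
       exclusions = if (nrow(ev$exclusion_log)) ev$exclusion_log else list(),
       clinical_threshold_mm = round(sphere_radius_from_volume(0.5)),
       conf_level = ev$conf_level)
}

#' Simulate and evaluate in one reproducible run
#'
#' Runs [run_simulate()] into `<out_dir>/dataset` and [run_evaluate()] into
#' `<out_dir>/evaluation`. Stage failures propagate with the stage name
#' prefixed to the error message.
#'
#' @inheritParams run_simulate
#' @inheritParams run_evaluate
#' @return The `"biopsy_evaluation"`, invisibly.
#' @export
run_end_to_end <- function(config, out_dir, seed = NULL, conf_level = 0.95) {
  stage <- function(name, expr) {
    withCallingHandlers(expr, error = function(e) {
      e$message <- paste0("[", name, "] ", conditionMessage(e))
      stop(e)
    })
  }
  stage("simulate", run_simulate(config, file.path(out_dir, "dataset"),
                                 seed = seed))
  stage("evaluate", run_evaluate(file.path(out_dir, "dataset"),
                                 file.path(out_dir, "evaluation"),
                                 conf_level = conf_level))
}
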