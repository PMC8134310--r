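# On-disk formats: YAML experiment configuration, CSV dataset tables, JSON
# summaries and manifests. These are the interchange dialects between the
# simulation and evaluation stages and for importing real pick tables.

#' Write / read an experiment configuration as YAML
#'
#' The configuration file has blocks `template` (spacing and hole counts),
#' `fiducials` (label + xyz mm triples), `kit` (throw, core length, tip to
#' core center), `noise`, `experiment` (phantom volumes, needles per
#' phantom, observer counts, excluded-entry needles) and `seed`.
#'
#' @param config An [experiment_config()].
#' @param path File path for the YAML.
#' @return `write_config` returns `path` invisibly; `read_config` returns an
#'   [experiment_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  fid <- lapply(seq_along(config$fiducials$labels), function(i) {
    p <- config$fiducials$positions[[i]]$xyz
    list(label = config$fiducials$labels[i],
         x_mm = p[1], y_mm = p[2], z_mm = p[3])
  })
  obj <- list(
    template = list(spacing_mm = config$grid$spacing_mm,
                    n_rows = config$grid$n_rows, n_cols = config$grid$n_cols),
    fiducials = fid,
    kit = list(throw_mm = config$kit$throw_mm,
               core_length_mm = config$kit$core_length_mm,
               tip_to_core_center_mm = config$kit$tip_to_core_center_mm),
    noise = unclass(config$noise),
    experiment = list(volumes_cc = config$volumes_cc,
                      needles_per_phantom = config$needles_per_phantom,
                      n_gt_observers = config$n_gt_observers,
                      n_cal_observers = config$n_cal_observers,
                      invisible_needles = as.list(config$invisible_needles)),
    seed = config$seed)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .config_error("config file not found: ", path)
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) .config_error("config is not valid YAML: ",
                                                    conditionMessage(e)))
  need <- c("template", "fiducials", "kit", "noise", "experiment", "seed")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    .config_error("config is missing required key(s): ",
                  paste(miss, collapse = ", "))
  }
  tm <- obj$template
  grid <- template_grid(spacing_mm = tm$spacing_mm,
                        n_rows = tm$n_rows, n_cols = tm$n_cols)
  fid <- fiducial_set(lapply(obj$fiducials, function(f)
    pt3(f$x_mm, f$y_mm, f$z_mm, frame = "TEMPLATE")),
    labels = vapply(obj$fiducials, `[[`, "", "label"))
  kit <- biopsy_kit(throw_mm = obj$kit$throw_mm,
                    core_length_mm = obj$kit$core_length_mm,
                    tip_to_core_center_mm = obj$kit$tip_to_core_center_mm)
  nm <- do.call(noise_model, obj$noise)
  ex <- obj$experiment
  experiment_config(volumes_cc = unlist(ex$volumes_cc),
                    needles_per_phantom = unlist(ex$needles_per_phantom),
                    n_gt_observers = ex$n_gt_observers,
                    n_cal_observers = ex$n_cal_observers,
                    noise = nm, kit = kit, grid = grid, fiducials = fid,
                    invisible_needles = unlist(ex$invisible_needles),
                    seed = obj$seed)
}

.DATASET_FILES <- list(
  plans = c("phantom_id", "needle_id", "row_label", "col_label", "depth_mm"),
  targets = c("phantom_id", "needle_id", "x_mm", "y_mm", "z_mm", "frame"),
  truth_cores = c("phantom_id", "needle_id", "center_x_mm", "center_y_mm",
                  "center_z_mm", "dir_x", "dir_y", "dir_z", "frame"),
  fiducial_picks = c("phantom_id", "observer_id", "label", "x_mm", "y_mm",
                     "z_mm", "frame"),
  gt_picks = c("phantom_id", "observer_id", "needle_id", "point_kind",
               "x_mm", "y_mm", "z_mm", "frame", "visible"),
  landmarks = c("phantom_id", "label", "frame", "x_mm", "y_mm", "z_mm"))

#' Write / read an experiment dataset directory
#'
#' A dataset directory holds `config.yaml` plus one CSV per table
#' (`plans.csv`, `targets.csv`, `truth_cores.csv`, `fiducial_picks.csv`,
#' `gt_picks.csv`, `landmarks.csv`) and `truth_transforms.json` with the
#' generating frame transforms (provenance only; evaluation never reads
#' them). `read_experiment` validates each file's schema and reports the
#' offending file and columns on failure.
#'
#' @param exp A `"biopsy_experiment"`.
#' @param dir Dataset directory (created if needed).
#' @return `write_experiment` returns `dir` invisibly; `read_experiment`
#'   returns a `"biopsy_experiment"`.
#' @export
write_experiment <- function(exp, dir) {
  stopifnot(inherits(exp, "biopsy_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(exp$config, file.path(dir, "config.yaml"))
  for (nm in names(.DATASET_FILES)) {
    utils::write.csv(exp[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  truth <- lapply(exp$phantoms, function(ph) {
    list(phantom_id = ph$phantom_id, volume_cc = ph$spec$volume_cc,
         true_cal = if (!is.null(ph$true_cal)) rt_serialize(ph$true_cal),
         true_ref = if (!is.null(ph$true_ref)) rt_serialize(ph$true_ref))
  })
  jsonlite::write_json(list(phantoms = truth, n_resampled = exp$n_resampled),
                       file.path(dir, "truth_transforms.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  if (!dir.exists(dir)) .schema_error("dataset directory not found: ", dir)
  config <- read_config(file.path(dir, "config.yaml"))
  tabs <- list()
  for (nm in names(.DATASET_FILES)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) .schema_error("missing dataset file: ", basename(f))
    df <- utils::read.csv(f, stringsAsFactors = FALSE,
                          colClasses = c(needle_id = "character",
                                         phantom_id = "character")[
                            intersect(c("needle_id", "phantom_id"),
                                      .DATASET_FILES[[nm]])])
    miss <- setdiff(.DATASET_FILES[[nm]], names(df))
    if (length(miss)) {
      .schema_error(basename(f), " is missing column(s): ",
                    paste(miss, collapse = ", "))
    }
    tabs[[nm]] <- df
  }
  phantoms <- lapply(seq_along(config$volumes_cc), function(i) {
    list(phantom_id = paste0("P", i), spec = phantom_spec(config$volumes_cc[i]),
         true_cal = NULL, true_ref = NULL)
  })
  n_res <- 0L
  tf <- file.path(dir, "truth_transforms.json")
  if (file.exists(tf)) {
    truth <- jsonlite::read_json(tf)
    n_res <- as.integer(truth$n_resampled %||% 0L)
    for (i in seq_along(truth$phantoms)) {
      tp <- truth$phantoms[[i]]
      j <- match(tp$phantom_id, vapply(phantoms, `[[`, "", "phantom_id"))
      if (!is.na(j)) {
        if (!is.null(tp$true_cal)) phantoms[[j]]$true_cal <- rt_deserialize(tp$true_cal)
        if (!is.null(tp$true_ref)) phantoms[[j]]$true_ref <- rt_deserialize(tp$true_ref)
      }
    }
  }
  structure(c(list(config = config, phantoms = phantoms), tabs,
              list(n_resampled = n_res)),
            class = "biopsy_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records what produced a directory's contents: the package version, the
#' seed, an MD5 of the configuration, and an MD5 inventory of every file,
#' so that a re-run with the same inputs can be verified byte-for-byte.
#'
#' @param dir Directory to inventory; the manifest is written inside it.
#' @param seed Integer seed used for the run.
#' @param extra Optional named list merged into the manifest (e.g. an
#'   exclusion log).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(dir, seed, extra = list()) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  cfg <- file.path(dir, "config.yaml")
  manifest <- c(list(
    package = "biopsynav",
    version = as.character(utils::packageVersion("biopsynav")),
    seed = seed,
    config_md5 = if (file.exists(cfg)) unname(tools::md5sum(cfg)) else NULL,
    files = as.list(sums)), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Verify a directory against its manifest
#' @param dir Directory containing `manifest.json`.
#' @return `TRUE` if every inventoried file matches its checksum; otherwise
#'   an error naming the first mismatch.
#' @export
verify_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) .schema_error("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf)
  for (f in names(manifest$files)) {
    actual <- unname(tools::md5sum(file.path(dir, f)))
    if (is.na(actual) || actual != manifest$files[[f]]) {
      .schema_error("manifest mismatch for ", f)
    }
  }
  TRUE
}
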