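# End-to-end evaluation: calibrate per observer, rebuild planned cores from
# the recorded plans, form consensus ground truth, register frames, compute
# both error metrics, apply exclusions and summarize.

#' Evaluate navigation accuracy for a (synthetic or imported) experiment
#'
#' Runs the complete accuracy analysis on an experiment dataset:
#' \enumerate{
#'   \item per phantom, register the reference frame to the low-field frame
#'     from the box-corner landmark picks;
#'   \item per phantom and calibrating observer, calibrate the template from
#'     that observer's fiducial picks;
#'   \item per needle, rebuild the planned core from the recorded grid
#'     coordinate and depth under each observer's calibration, extrapolate
#'     and average the ground-truth core from the ground-truth observers'
#'     entry/tip picks, and compute the center-to-center, point-to-line and
#'     point-to-segment errors;
#'   \item exclude needles whose entry point was flagged as not
#'     visualizable (logged, never silent) and summarize the kept records.
#' }
#'
#' @param exp A `"biopsy_experiment"` from [generate_experiment()] or
#'   [read_experiment()].
#' @param conf_level Confidence level for summary CIs.
#' @return An object of class `"biopsy_evaluation"`: list with `records`
#'   (every record, exclusions flagged), `kept`, `excluded`, `summaries`
#'   (one [summarize_errors()] per metric), `interobserver` (named variance
#'   vector, mm^2), `gt_stats` ([interobserver_pick_stats()] over tip
#'   picks), `calibrations` (per phantom x observer FRE table),
#'   `registrations` (per-phantom transform + FRE), and `exclusion_log`.
#' @export
evaluate_experiment <- function(exp, conf_level = 0.95) {
  stopifnot(inherits(exp, "biopsy_experiment"))
  cfg <- exp$config
  grid <- cfg$grid
  kit <- cfg$kit
  metrics <- c("center_to_center_mm", "point_to_line_mm", "point_to_segment_mm")

  # frame registration per phantom from landmark picks
  registrations <- list()
  for (ph in exp$phantoms) {
    lm <- exp$landmarks[exp$landmarks$phantom_id == ph$phantom_id, ]
    if (nrow(lm) == 0L) {
      .schema_error("no landmarks for phantom ", ph$phantom_id)
    }
    labs <- sort(unique(lm$label))
    as_pts <- function(fr) {
      sub <- lm[lm$frame == fr, ]
      sub <- sub[match(labs, sub$label), ]
      if (anyNA(sub$x_mm)) {
        .schema_error("phantom ", ph$phantom_id,
                      ": landmark labels differ between frames")
      }
      lapply(seq_len(nrow(sub)),
             function(i) pt3(sub$x_mm[i], sub$y_mm[i], sub$z_mm[i], frame = fr))
    }
    registrations[[ph$phantom_id]] <-
      register_frames(as_pts("REFERENCE"), as_pts("LOWFIELD"))
  }

  # calibrations per phantom x observer
  cal_obs <- sort(unique(exp$fiducial_picks$observer_id))
  calibrations <- list()
  cal_rows <- list()
  for (ph in exp$phantoms) {
    for (ob in cal_obs) {
      sub <- exp$fiducial_picks[exp$fiducial_picks$phantom_id == ph$phantom_id &
                                exp$fiducial_picks$observer_id == ob, ]
      picked <- lapply(seq_len(nrow(sub)),
                       function(i) pt3(sub$x_mm[i], sub$y_mm[i], sub$z_mm[i],
                                       frame = "LOWFIELD"))
      cal <- calibrate(cfg$fiducials, picked, observer = ob,
                       labels = sub$label)
      calibrations[[paste(ph$phantom_id, ob, sep = ".")]] <- cal
      cal_rows[[length(cal_rows) + 1L]] <-
        data.frame(phantom_id = ph$phantom_id, observer_id = ob,
                   fre_mm = cal$fre, stringsAsFactors = FALSE)
    }
  }

  # consensus ground truth per needle; exclusion log
  picks <- .picks_from_table(exp$gt_picks)
  by_needle <- split(picks, vapply(picks, `[[`, "", "needle_id"))
  gt_cores <- list()
  excl <- list()
  for (nid in names(by_needle)) {
    ps <- by_needle[[nid]]
    any_invisible <- any(!vapply(ps, `[[`, TRUE, "visible_entry"))
    if (any_invisible) {
      excl[[length(excl) + 1L]] <- data.frame(
        needle_id = nid, reason = "entry point not visible on reference scan",
        stringsAsFactors = FALSE)
    }
    usable <- Filter(function(p) p$visible_entry, ps)
    gt_cores[[nid]] <- if (length(usable) > 0L) {
      average_ground_truth(usable, kit)
    } else {
      NULL
    }
  }
  exclusion_log <- if (length(excl)) do.call(rbind, excl) else
    data.frame(needle_id = character(), reason = character(),
               stringsAsFactors = FALSE)

  # error records: every needle x calibrating observer
  recs <- list()
  for (k in seq_len(nrow(exp$plans))) {
    plan <- exp$plans[k, ]
    reg <- registrations[[plan$phantom_id]]
    gt <- gt_cores[[plan$needle_id]]
    for (ob in cal_obs) {
      cal <- calibrations[[paste(plan$phantom_id, ob, sep = ".")]]
      core <- projected_core(c(plan$row_label, plan$col_label), plan$depth_mm,
                             grid, cal, kit)
      planned <- list(needle_id = plan$needle_id,
                      core_center = core$core_center)
      recs[[length(recs) + 1L]] <- if (is.null(gt)) {
        data.frame(needle_id = plan$needle_id, observer_id = ob,
                   center_to_center_mm = NA_real_, point_to_line_mm = NA_real_,
                   point_to_segment_mm = NA_real_, excluded = FALSE,
                   reason = "", stringsAsFactors = FALSE)
      } else {
        compute_errors(planned, gt, reg, observer_id = ob)
      }
    }
  }
  records <- do.call(rbind, recs)
  class(records) <- "data.frame"

  split_recs <- apply_exclusions(records, exclusion_log)
  if (nrow(split_recs$kept) == 0L) {
    .degenerate_error("every needle was excluded: nothing to summarize")
  }

  summaries <- lapply(metrics, function(m)
    summarize_errors(split_recs$kept, metric = m, conf_level = conf_level))
  names(summaries) <- metrics
  interobs <- vapply(metrics, function(m)
    interobserver_variance(split_recs$kept, metric = m), numeric(1))

  structure(list(records = rbind(split_recs$kept, split_recs$excluded),
                 kept = split_recs$kept, excluded = split_recs$excluded,
                 summaries = summaries, interobserver = interobs,
                 gt_stats = interobserver_pick_stats(exp$gt_picks),
                 calibrations = do.call(rbind, cal_rows),
                 registrations = registrations,
                 exclusion_log = exclusion_log,
                 conf_level = conf_level),
            class = "biopsy_evaluation")
}

#' @export
print.biopsy_evaluation <- function(x, ...) {
  labels <- c(center_to_center_mm = "Planned target to center of core",
              point_to_line_mm = "Planned target to core trajectory (line)",
              point_to_segment_mm = "Planned target to core segment")
  s <- x$summaries
  names(s) <- labels[names(s)]
  v <- x$interobserver
  names(v) <- labels[names(v)]
  cat(render_error_table(s, v), sep = "\n")
  cat("\n")
  cat(render_variability_table(x$gt_stats), sep = "\n")
  if (nrow(x$exclusion_log)) {
    cat("\nExcluded needles:\n")
    for (i in seq_len(nrow(x$exclusion_log))) {
      cat(sprintf("  %s: %s\n", x$exclusion_log$needle_id[i],
                  x$exclusion_log$reason[i]))
    }
  }
  invisible(x)
}
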