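# The two navigation error metrics per (needle x calibrating observer),
# exclusion handling, and Table-style summary statistics.

#' Navigation error between a planned core and a ground-truth core
#'
#' After mapping the ground-truth core from the reference frame into the
#' planned target's frame, three errors are computed: the center-to-center
#' distance between planned and true core centers; the perpendicular
#' distance from the planned target to the infinite line through the true
#' core (the headline point-to-line metric); and the clamped distance to the
#' finite core segment.
#'
#' @param planned A [plan_target()] result, or any list with `core_center`
#'   ([pt3()]) plus optional `needle_id`.
#' @param gt A ground-truth core ([extrapolate_core()] /
#'   [average_ground_truth()] result) in the `REFERENCE` frame.
#' @param frame_reg [register_frames()] result or [rigid_transform()]
#'   mapping `REFERENCE` into the planned target's frame.
#' @param observer_id Calibrating observer attributed to the planned core.
#' @return An object of class `"error_record"`: a one-row data frame with
#'   columns `needle_id`, `observer_id`, `center_to_center_mm`,
#'   `point_to_line_mm`, `point_to_segment_mm`, `excluded`, `reason`.
#' @export
compute_errors <- function(planned, gt, frame_reg, observer_id = "unknown") {
  stopifnot(inherits(gt, "ground_truth_core"))
  reg <- if (inherits(frame_reg, "rigid_transform")) frame_reg else frame_reg$transform
  stopifnot(inherits(reg, "rigid_transform"))
  target <- planned$core_center
  stopifnot(.is_pt3(target))
  center_m <- rt_apply(reg, gt$center)
  seg_m <- rt_apply(reg, gt$segment)
  if (center_m$frame != target$frame) {
    stop("registration maps into ", center_m$frame,
         " but the planned target is in ", target$frame, call. = FALSE)
  }
  rec <- data.frame(
    needle_id = if (!is.null(planned$needle_id)) planned$needle_id else gt$needle_id,
    observer_id = observer_id,
    center_to_center_mm = pt_distance(target, center_m),
    point_to_line_mm = point_line_distance(target, center_m, seg_direction(seg_m)),
    point_to_segment_mm = point_segment_distance(target, seg_m),
    excluded = FALSE, reason = "",
    stringsAsFactors = FALSE)
  class(rec) <- c("error_record", "data.frame")
  rec
}

#' Summary statistics for an error metric
#'
#' Mean, sample SD (n-1 denominator), min, max and the 95% confidence
#' interval of the mean, `mean +- t(0.975, n-1) * SD / sqrt(n)`, over the
#' non-excluded records. A single observation yields SD 0 with a degeneracy
#' flag and a warning rather than `NA`.
#'
#' @param x Numeric vector of errors (mm), or a data frame of error records.
#' @param metric When `x` is a data frame, the column to summarize (one of
#'   `"center_to_center_mm"`, `"point_to_line_mm"`, `"point_to_segment_mm"`).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `"summary_stats"`: list with `n`, `mean`,
#'   `sd`, `min`, `max`, `ci_low`, `ci_high`, `units`, `degenerate`.
#' @export
summarize_errors <- function(x, metric = "center_to_center_mm",
                             conf_level = 0.95) {
  if (is.data.frame(x)) {
    if (!metric %in% names(x)) {
      stop("no such metric column: ", metric, call. = FALSE)
    }
    if ("excluded" %in% names(x)) x <- x[!x$excluded, , drop = FALSE]
    x <- x[[metric]]
  }
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x)) {
    .degenerate_error("no non-excluded error values to summarize")
  }
  n <- length(x)
  m <- mean(x)
  degenerate <- n < 2L
  s <- if (degenerate) {
    warning("single observation: SD and CI are degenerate, reported as 0-width",
            call. = FALSE)
    0
  } else {
    stats::sd(x)
  }
  half <- if (degenerate) 0 else stats::qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n)
  structure(list(n = n, mean = m, sd = s, min = min(x), max = max(x),
                 ci_low = m - half, ci_high = m + half,
                 units = "mm", degenerate = degenerate),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d | mean %.2f | sd %.2f | min %.2f | max %.2f | 95%% CI [%.2f-%.2f] %s\n",
              x$n, x$mean, x$sd, x$min, x$max, x$ci_low, x$ci_high, x$units))
  invisible(x)
}

#' Interobserver variance of mean error
#'
#' The sample variance (n-1 denominator) of the per-observer mean errors:
#' how much the average navigation error depends on which physician
#' performed the template calibration.
#'
#' @param records Data frame of error records (non-excluded rows are used).
#' @param metric Error column to analyze.
#' @return Variance in mm^2.
#' @export
interobserver_variance <- function(records, metric = "center_to_center_mm") {
  stopifnot(is.data.frame(records), metric %in% names(records))
  if ("excluded" %in% names(records)) {
    records <- records[!records$excluded, , drop = FALSE]
  }
  means <- tapply(records[[metric]], records$observer_id, mean)
  if (length(means) < 2L) {
    .degenerate_error("interobserver variance needs at least 2 observers, got ",
                      length(means))
  }
  stats::var(as.numeric(means))
}

#' Apply needle-level exclusions to error records
#'
#' A needle whose ground truth is unusable (e.g. its entry point could not
#' be visualized on the reference scan) invalidates every record of that
#' needle, across all calibrating observers. Excluded records are flagged
#' and retained with their reason, never deleted.
#'
#' @param records Data frame of error records.
#' @param exclusions Data frame with columns `needle_id` and `reason` (may
#'   have zero rows).
#' @return A list with `kept` and `excluded` data frames; `excluded` rows
#'   carry `excluded = TRUE` and the reason.
#' @export
apply_exclusions <- function(records, exclusions = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(exclusions) || nrow(exclusions) == 0L) {
    return(list(kept = records,
                excluded = records[0, , drop = FALSE]))
  }
  stopifnot(all(c("needle_id", "reason") %in% names(exclusions)))
  hit <- records$needle_id %in% exclusions$needle_id
  out <- records
  out$excluded[hit] <- TRUE
  out$reason[hit] <- exclusions$reason[match(out$needle_id[hit],
                                             exclusions$needle_id)]
  list(kept = out[!hit, , drop = FALSE],
       excluded = out[hit, , drop = FALSE])
}

# fixed row labels of the rendered summary tables
.ERROR_TABLE_LABELS <- c("Number of samples", "Average error (mm)", "Min (mm)",
                    "Max (mm)", "Standard deviation (mm)",
                    "95% confidence interval", "Interobserver variance (mm^2)")
.VARIABILITY_TABLE_LABELS <- c("Number of needles",
                    "Average distance between selected points across the users (mm)",
                    "Min distance between selected points across the users (mm)",
                    "Max distance between selected points across the users (mm)",
                    "Standard deviation")

#' Render the error-measurement summary table as text
#'
#' Produces the fixed-row-label plain-text table of the navigation error
#' results, one column per metric, values at 2-decimal mm precision.
#'
#' @param summaries Named list of [summarize_errors()] results, e.g.
#'   `list("Planned target to center of core" = ..., "Planned target to core
#'   segment" = ...)`.
#' @param variances Named numeric vector of interobserver variances (mm^2),
#'   same names/order as `summaries`.
#' @return Character vector of table lines (also printed invisibly-friendly).
#' @export
render_error_table <- function(summaries, variances) {
  stopifnot(length(summaries) == length(variances))
  cols <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    c(sprintf("%d", s$n), sprintf("%.2f", s$mean), sprintf("%.2f", s$min),
      sprintf("%.2f", s$max), sprintf("%.2f", s$sd),
      sprintf("[%.2f-%.2f]", s$ci_low, s$ci_high),
      format(variances[[i]], digits = 2))
  })
  header <- c("Error measurement", names(summaries))
  body <- cbind(.ERROR_TABLE_LABELS, do.call(cbind, cols))
  .format_text_table(header, body)
}

#' Render the ground-truth user-variability table as text
#'
#' @param stats An [interobserver_pick_stats()] result.
#' @return Character vector of table lines.
#' @export
render_variability_table <- function(stats) {
  vals <- c(sprintf("%d", stats$n_needles), sprintf("%.2f", stats$mean),
            sprintf("%.2f", stats$min), sprintf("%.2f", stats$max),
            sprintf("%.2f", stats$sd))
  .format_text_table(c("Ground truth user variability item", "Result"),
                     cbind(.VARIABILITY_TABLE_LABELS, vals))
}

.format_text_table <- function(header, body) {
  m <- rbind(header, body)
  widths <- apply(nchar(m), 2, max)
  fmt_row <- function(r) paste(mapply(formatC, r, width = widths,
                                      flag = "-"), collapse = "  ")
  lines <- apply(m, 1, fmt_row)
  c(lines[1], paste(rep("-", nchar(lines[1])), collapse = ""), lines[-1])
}
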