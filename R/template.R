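# The transperineal grid template, its fiducials, calibration into the
# low-field image frame, virtual-grid hole positions, target snapping and
# cannula depth / projected core computation.

#' Construct a transperineal template grid
#'
#' The template is a rigid plate of regularly spaced guide holes; needles
#' inserted through a hole travel along a straight line normal to the plate.
#' Holes are addressed by a row label (letters by convention) and a column
#' label (numbers by convention). The grid is defined in the `TEMPLATE` frame
#' and carried into an image frame by a calibration transform.
#'
#' @param spacing_mm Center-to-center hole pitch, mm (standard clinical
#'   grids use 5 mm).
#' @param n_rows,n_cols Number of hole rows / columns.
#' @param row_labels,col_labels Ordered label vectors (lengths must match the
#'   counts); defaults are letters A... for rows and "1"... for columns.
#' @param origin_hole Position of hole (row 1, col 1) in the `TEMPLATE`
#'   frame; default centers the grid on the origin with the plate in the
#'   z = 0 plane.
#' @param axis_row,axis_col In-plane unit directions of increasing row /
#'   column index.
#' @param needle_axis Unit insertion direction (grid normal, pointing into
#'   the patient). The three axes must be mutually orthogonal.
#' @return An object of class `"template_grid"`.
#' @examples
#' g <- template_grid()
#' hole_position(g, c("A", "1"))
#' @export
template_grid <- function(spacing_mm = 5,
                          n_rows = 13, n_cols = 13,
                          row_labels = LETTERS[seq_len(n_rows)],
                          col_labels = as.character(seq_len(n_cols)),
                          origin_hole = NULL,
                          axis_row = c(0, 1, 0),
                          axis_col = c(1, 0, 0),
                          needle_axis = c(0, 0, 1)) {
  stopifnot(spacing_mm > 0, n_rows >= 1, n_cols >= 1)
  if (length(row_labels) != n_rows || length(col_labels) != n_cols) {
    stop("label vectors must match n_rows / n_cols", call. = FALSE)
  }
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels)) {
    stop("row and column labels must be unique", call. = FALSE)
  }
  axis_row <- unclass(dir3(axis_row))
  axis_col <- unclass(dir3(axis_col))
  needle_axis <- unclass(dir3(needle_axis))
  dots <- c(sum(axis_row * axis_col), sum(axis_row * needle_axis),
            sum(axis_col * needle_axis))
  if (max(abs(dots)) > 1e-9) {
    stop("grid axes must be mutually orthogonal", call. = FALSE)
  }
  if (is.null(origin_hole)) {
    origin_hole <- pt3(-(n_cols - 1) / 2 * spacing_mm * axis_col -
                       (n_rows - 1) / 2 * spacing_mm * axis_row,
                       frame = "TEMPLATE")
  }
  stopifnot(.is_pt3(origin_hole), origin_hole$frame == "TEMPLATE")
  structure(list(spacing_mm = spacing_mm, n_rows = n_rows, n_cols = n_cols,
                 row_labels = as.character(row_labels),
                 col_labels = as.character(col_labels),
                 origin_hole = origin_hole, axis_row = axis_row,
                 axis_col = axis_col, needle_axis = needle_axis),
            class = "template_grid")
}

#' @export
print.template_grid <- function(x, ...) {
  cat(sprintf("<template_grid> %d x %d holes, %.1f mm pitch, rows %s-%s, cols %s-%s\n",
              x$n_rows, x$n_cols, x$spacing_mm,
              x$row_labels[1], x$row_labels[x$n_rows],
              x$col_labels[1], x$col_labels[x$n_cols]))
  invisible(x)
}

# resolve a (row_label, col_label) pair to 1-based indices
.grid_indices <- function(grid, coord) {
  coord <- as.character(unlist(coord, use.names = FALSE))
  if (length(coord) != 2L) {
    stop("grid coordinate must be a (row_label, col_label) pair", call. = FALSE)
  }
  ri <- match(coord[1], grid$row_labels)
  ci <- match(coord[2], grid$col_labels)
  if (is.na(ri)) stop("unknown row label '", coord[1], "'", call. = FALSE)
  if (is.na(ci)) stop("unknown column label '", coord[2], "'", call. = FALSE)
  c(row = ri, col = ci)
}

# template-frame coordinates of every hole, rows outer (row-major), as a
# (n_rows*n_cols) x 3 matrix; row order encodes the snapping tie-break.
.grid_holes_mat <- function(grid) {
  # expand.grid varies its first factor fastest: columns inner, rows outer
  idx <- expand.grid(col = seq_len(grid$n_cols), row = seq_len(grid$n_rows))
  o <- grid$origin_hole$xyz
  M <- matrix(o, nrow(idx), 3, byrow = TRUE) +
    grid$spacing_mm * (outer(idx$row - 1, grid$axis_row) +
                       outer(idx$col - 1, grid$axis_col))
  attr(M, "row_index") <- idx$row
  attr(M, "col_index") <- idx$col
  M
}

#' Position of a template hole, optionally mapped through a calibration
#'
#' @param grid A [template_grid()].
#' @param coord A `(row_label, col_label)` pair, e.g. `c("G", "7")`.
#' @param cal Optional [calibrate()] result (or [rigid_transform()]
#'   `TEMPLATE -> LOWFIELD`); if supplied, the hole is returned in the
#'   `LOWFIELD` frame, otherwise in `TEMPLATE`.
#' @return The hole center as a [pt3()].
#' @export
hole_position <- function(grid, coord, cal = NULL) {
  stopifnot(inherits(grid, "template_grid"))
  ij <- .grid_indices(grid, coord)
  p <- pt3(grid$origin_hole$xyz +
           (ij["row"] - 1) * grid$spacing_mm * grid$axis_row +
           (ij["col"] - 1) * grid$spacing_mm * grid$axis_col,
           frame = "TEMPLATE")
  if (is.null(cal)) p else rt_apply(.cal_transform(cal), p)
}

.cal_transform <- function(cal) {
  if (inherits(cal, "calibration_result")) return(cal$transform)
  if (inherits(cal, "rigid_transform")) return(cal)
  stop("'cal' must be a calibration_result or rigid_transform", call. = FALSE)
}

#' Construct a fiducial set
#'
#' Fiducial markers are enclosed in the template holder at known positions in
#' the `TEMPLATE` frame; picking them on the image calibrates the template.
#' At least 3 non-collinear fiducials are required for a unique rigid fit.
#'
#' @param positions List of [pt3()] in the `TEMPLATE` frame (>= 3,
#'   non-collinear).
#' @param labels Character identifiers, one per fiducial.
#' @return An object of class `"fiducial_set"`.
#' @export
fiducial_set <- function(positions, labels = paste0("F", seq_along(positions))) {
  stopifnot(is.list(positions), length(positions) >= 3L,
            length(labels) == length(positions))
  if (!all(vapply(positions, function(p) .is_pt3(p) && p$frame == "TEMPLATE", TRUE))) {
    stop("fiducial positions must be pt3 objects in the TEMPLATE frame",
         call. = FALSE)
  }
  P <- do.call(rbind, lapply(positions, `[[`, "xyz"))
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("fiducials are collinear: calibration would be underdetermined",
         call. = FALSE)
  }
  structure(list(positions = positions, labels = as.character(labels)),
            class = "fiducial_set")
}

#' Default synthetic fiducial geometry
#'
#' Three fiducials to the left, right and top of the grid, mirroring the
#' layout of a template holder with markers enclosed on three sides. The true
#' coordinates of any commercial holder are proprietary, so these positions
#' are synthetic stand-ins at a realistic scale.
#'
#' @return A [fiducial_set()] with labels `"left"`, `"right"`, `"top"`.
#' @export
default_fiducials <- function() {
  fiducial_set(list(pt3(-45, 5, 0, frame = "TEMPLATE"),
                    pt3(45, 5, 0, frame = "TEMPLATE"),
                    pt3(0, 48, 0, frame = "TEMPLATE")),
               labels = c("left", "right", "top"))
}

#' Biopsy needle kit geometry
#'
#' Dimensions of the spring-fired core biopsy kit that turn a cannula
#' insertion depth into the geometry of the sampled core: when the gun fires,
#' the needle advances `throw_mm` beyond the cannula tip and captures a core
#' of `core_length_mm` whose center sits `tip_to_core_center_mm` beyond the
#' cannula tip along the needle axis.
#'
#' @param throw_mm Needle fire travel, mm.
#' @param core_length_mm Length of the sampled tissue core, mm (cannot
#'   exceed the throw).
#' @param tip_to_core_center_mm Offset from cannula tip to core center along
#'   the needle axis, mm; defaults to half the throw.
#' @return An object of class `"biopsy_kit"`.
#' @export
biopsy_kit <- function(throw_mm = 20, core_length_mm = 18,
                       tip_to_core_center_mm = throw_mm / 2) {
  stopifnot(throw_mm > 0, core_length_mm > 0)
  if (core_length_mm > throw_mm + 1e-9) {
    stop("core_length_mm cannot exceed the needle throw", call. = FALSE)
  }
  structure(list(throw_mm = throw_mm, core_length_mm = core_length_mm,
                 tip_to_core_center_mm = tip_to_core_center_mm),
            class = "biopsy_kit")
}

#' Calibrate the template into the low-field image frame
#'
#' Matches picked fiducial positions on the image to the known fiducial
#' geometry (correspondence by label) and computes the rigid
#' `TEMPLATE -> LOWFIELD` transform by least squares ([fit_rigid()]). The
#' fiducial registration error (FRE) is the RMS residual of the fit.
#'
#' @param known A [fiducial_set()] (template-frame truth).
#' @param picked List of [pt3()] in the `LOWFIELD` frame; matched to `known`
#'   by `labels` if supplied, else by position.
#' @param observer Identifier of the picking observer.
#' @param labels Optional character labels for `picked`.
#' @return An object of class `"calibration_result"`: fields `transform`,
#'   `fre` (mm) and `observer`.
#' @export
calibrate <- function(known, picked, observer = "unknown", labels = NULL) {
  stopifnot(inherits(known, "fiducial_set"))
  if (length(picked) != length(known$positions)) {
    stop("picked fiducial count (", length(picked),
         ") does not match the known set (", length(known$positions), ")",
         call. = FALSE)
  }
  if (!is.null(labels)) {
    ord <- match(known$labels, labels)
    if (anyNA(ord)) {
      stop("picked fiducial labels do not cover the known set: missing ",
           paste(known$labels[is.na(ord)], collapse = ", "), call. = FALSE)
    }
    picked <- picked[ord]
  }
  fit <- fit_rigid(known$positions, picked)
  structure(list(transform = fit$transform, fre = fit$fre, observer = observer),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> observer %s, FRE %.4f mm\n", x$observer, x$fre))
  print(x$transform)
  invisible(x)
}

#' Snap a clicked target to the nearest template needle trajectory
#'
#' Planning clicks land anywhere in the image; the needle can only travel
#' along one of the template's hole axes. The planned coordinate is the grid
#' hole whose (calibrated) needle line passes closest to the click. Ties are
#' broken toward the lowest row label, then the lowest column label.
#'
#' @param click The clicked target as a [pt3()] in the `LOWFIELD` frame.
#' @param grid A [template_grid()].
#' @param cal Calibration (`TEMPLATE -> LOWFIELD`): a [calibrate()] result or
#'   [rigid_transform()].
#' @return A list with `grid_coord` (named character vector `row`, `col`),
#'   `distance_mm` (perpendicular click-to-line distance), and `trajectory`
#'   (list with `point` [pt3()] on the grid plane and `dir` [dir3()], both in
#'   `LOWFIELD`).
#' @export
snap_target <- function(click, grid, cal) {
  stopifnot(.is_pt3(click), inherits(grid, "template_grid"))
  if (click$frame != "LOWFIELD") {
    stop("click must be in the LOWFIELD frame, got ", click$frame, call. = FALSE)
  }
  tr <- .cal_transform(cal)
  H <- .rt_apply_mat(tr, .grid_holes_mat(grid))        # holes in LOWFIELD
  u <- drop(tr$rotation %*% grid$needle_axis)          # common line direction
  V <- sweep(H, 2, click$xyz, "-")                     # hole - click
  # |v x u| with |u| = 1, vectorized over holes
  cx <- V[, 2] * u[3] - V[, 3] * u[2]
  cy <- V[, 3] * u[1] - V[, 1] * u[3]
  cz <- V[, 1] * u[2] - V[, 2] * u[1]
  d <- sqrt(cx^2 + cy^2 + cz^2)
  best <- which(d <= min(d) + 1e-9)[1L]   # row-major order = tie-break rule
  Mtpl <- .grid_holes_mat(grid)
  coord <- c(row = grid$row_labels[attr(Mtpl, "row_index")[best]],
             col = grid$col_labels[attr(Mtpl, "col_index")[best]])
  list(grid_coord = coord,
       distance_mm = d[best],
       trajectory = list(point = pt3(H[best, ], frame = "LOWFIELD"),
                         dir = dir3(u)))
}

#' Cannula insertion depth placing a target at the core center
#'
#' The depth readout is the distance to insert the cannula along the hole
#' axis, measured from the grid plane (the patient-side face of the
#' template), such that after firing, the center of the sampled core
#' coincides with the on-axis projection of the target. Because the core
#' center sits `tip_to_core_center_mm` beyond the cannula tip, the depth is
#' the target's axial distance minus that offset.
#'
#' @param target_point Target as a [pt3()] in the `LOWFIELD` frame.
#' @param grid_coord `(row_label, col_label)` pair of the planned hole.
#' @param grid A [template_grid()].
#' @param cal Calibration (`TEMPLATE -> LOWFIELD`).
#' @param kit A [biopsy_kit()].
#' @return Depth in mm (> 0).
#' @export
compute_depth <- function(target_point, grid_coord, grid, cal, kit) {
  stopifnot(.is_pt3(target_point), inherits(kit, "biopsy_kit"))
  tr <- .cal_transform(cal)
  p_tpl <- rt_apply(rt_invert(tr), target_point)
  h_tpl <- hole_position(grid, grid_coord)
  s <- sum((p_tpl$xyz - h_tpl$xyz) * grid$needle_axis)
  depth <- s - kit$tip_to_core_center_mm
  if (depth <= 0) {
    stop(sprintf("target is proximal to the template (depth %.2f mm <= 0)", depth),
         call. = FALSE)
  }
  depth
}

#' Projected biopsy core for a grid coordinate and depth
#'
#' Reconstructs, in the `LOWFIELD` frame, the core that a needle fired
#' through the given hole at the given cannula depth would sample: the
#' cannula tip sits `depth` mm beyond the grid plane along the hole axis, the
#' core center `tip_to_core_center_mm` further, and the core is a segment of
#' `core_length_mm` centered there. This is how a recorded plan is
#' retroactively turned into planned-target coordinates under any observer's
#' calibration.
#'
#' @inheritParams compute_depth
#' @param depth Cannula insertion depth, mm (> 0).
#' @return A list with `core` ([seg3()]), `core_center`, `tip` (both
#'   [pt3()]), and `direction` ([dir3()]), all in `LOWFIELD`.
#' @export
projected_core <- function(grid_coord, depth, grid, cal, kit) {
  stopifnot(inherits(grid, "template_grid"), inherits(kit, "biopsy_kit"))
  if (!is.numeric(depth) || depth <= 0) {
    stop("depth must be a positive number of mm", call. = FALSE)
  }
  tr <- .cal_transform(cal)
  h_tpl <- hole_position(grid, grid_coord)
  ax <- grid$needle_axis
  tip_tpl <- h_tpl$xyz + depth * ax
  center_tpl <- tip_tpl + kit$tip_to_core_center_mm * ax
  half <- kit$core_length_mm / 2
  a_tpl <- pt3(center_tpl - half * ax, frame = "TEMPLATE")
  b_tpl <- pt3(center_tpl + half * ax, frame = "TEMPLATE")
  list(core = seg3(rt_apply(tr, a_tpl), rt_apply(tr, b_tpl)),
       core_center = rt_apply(tr, pt3(center_tpl, frame = "TEMPLATE")),
       tip = rt_apply(tr, pt3(tip_tpl, frame = "TEMPLATE")),
       direction = rt_apply(tr, dir3(ax)))
}

#' Plan a target from a click
#'
#' Convenience composition of [snap_target()], [compute_depth()] and
#' [projected_core()]: snaps the click to the nearest needle trajectory,
#' computes the depth readout, and records the planned core.
#'
#' @inheritParams snap_target
#' @param kit A [biopsy_kit()].
#' @param needle_id Identifier for the planned needle.
#' @return An object of class `"planned_target"`: fields `needle_id`,
#'   `click`, `grid_coord`, `depth_mm`, `core`, `core_center`.
#' @export
plan_target <- function(click, grid, cal, kit, needle_id = "N1") {
  snap <- snap_target(click, grid, cal)
  depth <- compute_depth(click, snap$grid_coord, grid, cal, kit)
  core <- projected_core(snap$grid_coord, depth, grid, cal, kit)
  structure(list(needle_id = needle_id, click = click,
                 grid_coord = snap$grid_coord, depth_mm = depth,
                 core = core$core, core_center = core$core_center),
            class = "planned_target")
}
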