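# Seeded synthetic phantom experiments: prostate phantoms, true frame
# transforms, planned targets, realized (deflected) needles, and noisy
# fiducial / ground-truth / landmark picks with through-plane slice
# quantization. The generator reproduces the statistical structure the
# accuracy analysis assumes, so the full pipeline runs without scanner data.

#' Observation noise model for the synthetic experiment
#'
#' Pick noise is isotropic Gaussian in the image plane (x, y); the
#' through-plane coordinate is not noisy but quantized to the scan's slice
#' centers, reflecting that observers select points on discrete slices.
#' Needle deflection is a single angular kink at the template about a random
#' azimuth; depth error perturbs how far the cannula was actually inserted.
#'
#' @param fiducial_pick_sigma_mm In-plane SD of fiducial picks on the
#'   low-field scan, mm.
#' @param observer_pick_sigma_mm In-plane SD of needle entry/tip and
#'   landmark picks, mm.
#' @param lowfield_slice_mm Low-field scan slice spacing, mm.
#' @param reference_slice_mm Reference (1.5T) scan slice thickness, mm.
#' @param deflection_sigma_deg SD of the needle deflection angle, degrees.
#' @param depth_error_sigma_mm SD of the cannula insertion-depth error, mm.
#' @param quantize_slices Apply through-plane slice quantization to picks?
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(fiducial_pick_sigma_mm = 1.0,
                        observer_pick_sigma_mm = 1.0,
                        lowfield_slice_mm = 3.0,
                        reference_slice_mm = 3.48,
                        deflection_sigma_deg = 1.0,
                        depth_error_sigma_mm = 0.5,
                        quantize_slices = TRUE) {
  vals <- c(fiducial_pick_sigma_mm, observer_pick_sigma_mm,
            deflection_sigma_deg, depth_error_sigma_mm)
  if (any(vals < 0)) .config_error("noise SDs must be non-negative")
  if (lowfield_slice_mm <= 0 || reference_slice_mm <= 0) {
    .config_error("slice thicknesses must be positive")
  }
  structure(list(fiducial_pick_sigma_mm = fiducial_pick_sigma_mm,
                 observer_pick_sigma_mm = observer_pick_sigma_mm,
                 lowfield_slice_mm = lowfield_slice_mm,
                 reference_slice_mm = reference_slice_mm,
                 deflection_sigma_deg = deflection_sigma_deg,
                 depth_error_sigma_mm = depth_error_sigma_mm,
                 quantize_slices = isTRUE(quantize_slices)),
            class = "noise_model")
}

#' Noise-free observation model
#'
#' All noise SDs zero and slice quantization off: picks are exact, needles
#' go exactly where planned. Under this model every downstream error metric
#' is identically zero, which is the pipeline's strongest self-consistency
#' check.
#' @return A [noise_model()].
#' @export
noise_off <- function() {
  noise_model(fiducial_pick_sigma_mm = 0, observer_pick_sigma_mm = 0,
              deflection_sigma_deg = 0, depth_error_sigma_mm = 0,
              quantize_slices = FALSE)
}

#' Snap a coordinate to the nearest slice center
#'
#' Models through-plane quantization of observer picks: the z coordinate is
#' replaced by the nearest slice-center coordinate (slices at
#' `slice_origin + k * slice_mm`); in-plane coordinates are untouched. The
#' displacement never exceeds `slice_mm / 2`.
#'
#' @param p A [pt3()] point, or a numeric z coordinate.
#' @param slice_mm Slice spacing, mm (> 0).
#' @param slice_origin z of any slice center, mm.
#' @return Same type as `p`, with z quantized.
#' @export
quantize_to_slices <- function(p, slice_mm, slice_origin = 0) {
  if (slice_mm <= 0) .config_error("slice_mm must be positive")
  snap <- function(z) slice_origin + slice_mm * round((z - slice_origin) / slice_mm)
  if (.is_pt3(p)) {
    return(pt3(c(p$xyz[1], p$xyz[2], snap(p$xyz[3])), frame = p$frame))
  }
  snap(as.numeric(p))
}

#' Prostate phantom specification
#'
#' The phantom prostate is modeled as an ellipsoid of the requested volume
#' with fixed relative semi-axes, encased in a rectangular box whose corners
#' serve as registration landmarks. Shape detail beyond volume and extent is
#' irrelevant to navigation geometry, so no surface mesh is used.
#'
#' @param volume_cc Prostate volume, cm^3.
#' @param axis_ratios Relative semi-axes (x, y, z); scaled to match the
#'   volume.
#' @param center Ellipsoid center as a [pt3()] in the `TEMPLATE` frame;
#'   default places the gland 55 mm beyond the grid plane on the grid axis.
#' @param box_half_mm Half-dimensions of the phantom box, mm; the box is
#'   centered on the prostate and must contain it.
#' @return An object of class `"phantom_spec"` with fields `volume_cc`,
#'   `semi_axes_mm`, `center`, `box_half_mm`.
#' @export
phantom_spec <- function(volume_cc, axis_ratios = c(0.7, 1.0, 0.85),
                         center = pt3(0, 0, 55, frame = "TEMPLATE"),
                         box_half_mm = c(60, 60, 60)) {
  if (volume_cc <= 0) .config_error("phantom volume must be positive")
  stopifnot(length(axis_ratios) == 3L, all(axis_ratios > 0), .is_pt3(center))
  # volume in mm^3; 4/3 pi a b c = V with (a,b,c) = r * ratios
  r <- (3 * volume_cc * 1000 / (4 * pi * prod(axis_ratios)))^(1 / 3)
  semi <- r * axis_ratios
  if (any(semi > box_half_mm)) {
    .config_error("prostate ellipsoid does not fit inside the phantom box")
  }
  structure(list(volume_cc = volume_cc, semi_axes_mm = semi,
                 center = center, box_half_mm = box_half_mm),
            class = "phantom_spec")
}

#' Full synthetic experiment configuration
#'
#' Describes one accuracy study: the phantoms and how many needles go into
#' each, the observer panel, the hardware geometry and the noise model. The
#' seed fixes the entire random stream.
#'
#' @param volumes_cc Phantom prostate volumes, cm^3 (one phantom each).
#' @param needles_per_phantom Integer vector, same length as `volumes_cc`,
#'   each >= 1 (study phantoms received 3 or more).
#' @param n_gt_observers Ground-truth observers picking each needle
#'   (default 2).
#' @param n_cal_observers Calibrating physicians (default 4).
#' @param noise A [noise_model()].
#' @param kit A [biopsy_kit()].
#' @param grid A [template_grid()].
#' @param fiducials A [fiducial_set()].
#' @param invisible_needles Needle ids whose entry point is flagged as not
#'   visualizable on the reference scan (excluded from error analysis).
#' @param seed Integer root seed.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(volumes_cc = c(25, 40, 60, 90, 120),
                              needles_per_phantom = c(3, 3, 3, 4, 4),
                              n_gt_observers = 2,
                              n_cal_observers = 4,
                              noise = noise_model(),
                              kit = biopsy_kit(),
                              grid = template_grid(),
                              fiducials = default_fiducials(),
                              invisible_needles = character(),
                              seed = 1L) {
  if (length(volumes_cc) < 1L ||
      length(needles_per_phantom) != length(volumes_cc)) {
    .config_error("needles_per_phantom must match volumes_cc in length")
  }
  if (any(needles_per_phantom < 1L)) {
    .config_error("each phantom needs at least one needle")
  }
  if (n_gt_observers < 1L || n_cal_observers < 1L) {
    .config_error("observer counts must be at least 1")
  }
  stopifnot(inherits(noise, "noise_model"), inherits(kit, "biopsy_kit"),
            inherits(grid, "template_grid"), inherits(fiducials, "fiducial_set"))
  structure(list(volumes_cc = as.numeric(volumes_cc),
                 needles_per_phantom = as.integer(needles_per_phantom),
                 n_gt_observers = as.integer(n_gt_observers),
                 n_cal_observers = as.integer(n_cal_observers),
                 noise = noise, kit = kit, grid = grid, fiducials = fiducials,
                 invisible_needles = as.character(invisible_needles),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Default study-shaped configuration
#'
#' The canonical experiment shape: five phantoms of 25/40/60/90/120 cc,
#' needle counts {3, 3, 3, 4, 4} summing to 17, two ground-truth observers,
#' four calibrating physicians, and one needle (the last) flagged with a
#' non-visualizable entry point — leaving 16 usable needles and
#' 16 x 4 = 64 error records after exclusion.
#'
#' @param seed Integer root seed.
#' @param noise A [noise_model()]; default is the standard noise model.
#' @return An [experiment_config()].
#' @export
default_study_config <- function(seed = 1L, noise = noise_model()) {
  experiment_config(volumes_cc = c(25, 40, 60, 90, 120),
                    needles_per_phantom = c(3, 3, 3, 4, 4),
                    n_gt_observers = 2, n_cal_observers = 4,
                    noise = noise, invisible_needles = "N17", seed = seed)
}

# deterministic per-component child seeds so that toggling one noise source
# never shifts another component's draws (paired-seed comparisons)
.child_seed <- function(seed, k) {
  as.integer((abs(as.double(seed)) * 1103 + k * 7919) %% 2147483647)
}

# Euler ZYX rotation from angles in degrees
.rot_euler <- function(deg) {
  a <- deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# Rodrigues rotation of vector v by angle (rad) about unit axis
.rotate_about <- function(v, axis, angle) {
  v * cos(angle) + .cross3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

.in_ellipsoid <- function(xyz, spec) {
  sum(((xyz - spec$center$xyz) / spec$semi_axes_mm)^2) <= 1
}

# does the infinite line p0 + t*d intersect the ellipsoid?
.line_hits_ellipsoid <- function(p0, d, spec) {
  q <- (p0 - spec$center$xyz) / spec$semi_axes_mm
  w <- d / spec$semi_axes_mm
  a <- sum(w^2); b <- 2 * sum(q * w); cc <- sum(q^2) - 1
  b^2 - 4 * a * cc >= 0
}

.box_corners <- function(spec) {
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  sweep(as.matrix(s) * rep(spec$box_half_mm, each = 8), 2,
        -spec$center$xyz)
}

#' Generate a complete synthetic accuracy experiment
#'
#' Produces, deterministically for a given seed, everything the evaluation
#' stage consumes: per-phantom true frame transforms, planned targets
#' sampled uniformly inside each prostate ellipsoid and snapped to the
#' template grid, realized (deflected) needle cores, fiducial picks per
#' calibrating observer, ground-truth entry/tip picks per ground-truth
#' observer, and box-corner landmark picks in both frames. Independent
#' random sub-streams are used per component, so changing one noise SD does
#' not alter any other component's draws.
#'
#' A planned trajectory that misses the prostate entirely triggers a target
#' resample; the number of resamples is recorded in the result.
#'
#' @param config An [experiment_config()].
#' @return An object of class `"biopsy_experiment"`: a list of data frames
#'   (`plans`, `targets`, `truth_cores`, `fiducial_picks`, `gt_picks`,
#'   `landmarks`), the per-phantom truth (`phantoms`), the `config`, and
#'   `n_resampled`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  nm <- config$noise
  grid <- config$grid
  kit <- config$kit
  n_ph <- length(config$volumes_cc)

  # --- component 1: phantom specs and true frame transforms -----------------
  set.seed(.child_seed(config$seed, 1L))
  phantoms <- vector("list", n_ph)
  for (i in seq_len(n_ph)) {
    spec <- phantom_spec(config$volumes_cc[i])
    true_cal <- rigid_transform(.rot_euler(stats::runif(3, -10, 10)),
                                stats::runif(3, -20, 20),
                                "TEMPLATE", "LOWFIELD")
    true_ref <- rigid_transform(.rot_euler(stats::runif(3, -15, 15)),
                                stats::runif(3, -30, 30),
                                "LOWFIELD", "REFERENCE")
    phantoms[[i]] <- list(phantom_id = paste0("P", i), spec = spec,
                          true_cal = true_cal, true_ref = true_ref)
  }

  needle_ids <- sprintf("N%02d", seq_len(sum(config$needles_per_phantom)))
  needle_phantom <- rep(seq_len(n_ph), config$needles_per_phantom)

  # --- component 2: targets, snapping, planned depths -----------------------
  set.seed(.child_seed(config$seed, 2L))
  n_needles <- length(needle_ids)
  plans <- data.frame(phantom_id = paste0("P", needle_phantom),
                      needle_id = needle_ids,
                      row_label = character(n_needles),
                      col_label = character(n_needles),
                      depth_mm = numeric(n_needles),
                      stringsAsFactors = FALSE)
  targets <- plans[, c("phantom_id", "needle_id")]
  targets$x_mm <- NA_real_
  targets$y_mm <- NA_real_
  targets$z_mm <- NA_real_
  targets$frame <- "LOWFIELD"
  n_resampled <- 0L
  plan_tpl_entry <- matrix(NA_real_, n_needles, 3)  # hole position, TEMPLATE
  for (k in seq_len(n_needles)) {
    ph <- phantoms[[needle_phantom[k]]]
    repeat {
      # uniform point in the unit ball, scaled to the ellipsoid
      repeat {
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) <= 1) break
      }
      tgt_tpl <- ph$spec$center$xyz + u * ph$spec$semi_axes_mm
      click <- rt_apply(ph$true_cal, pt3(tgt_tpl, frame = "TEMPLATE"))
      snap <- snap_target(click, grid, ph$true_cal)
      hole_tpl <- hole_position(grid, snap$grid_coord)
      if (.line_hits_ellipsoid(hole_tpl$xyz, grid$needle_axis, ph$spec)) {
        depth <- compute_depth(click, snap$grid_coord, grid, ph$true_cal, kit)
        break
      }
      n_resampled <- n_resampled + 1L
    }
    plans$row_label[k] <- snap$grid_coord[["row"]]
    plans$col_label[k] <- snap$grid_coord[["col"]]
    plans$depth_mm[k] <- depth
    targets$x_mm[k] <- click$xyz[1]
    targets$y_mm[k] <- click$xyz[2]
    targets$z_mm[k] <- click$xyz[3]
    plan_tpl_entry[k, ] <- hole_tpl$xyz
  }

  # --- component 3: needle execution (deflection + depth error) -------------
  set.seed(.child_seed(config$seed, 3L))
  truth <- vector("list", n_needles)
  for (k in seq_len(n_needles)) {
    ph <- phantoms[[needle_phantom[k]]]
    theta <- stats::rnorm(1) * nm$deflection_sigma_deg * pi / 180
    phi <- stats::runif(1, 0, 2 * pi)
    depth_err <- stats::rnorm(1) * nm$depth_error_sigma_mm
    kink_axis <- cos(phi) * grid$axis_col + sin(phi) * grid$axis_row
    u <- .rotate_about(grid$needle_axis, kink_axis, theta)
    entry_tpl <- plan_tpl_entry[k, ]
    tip_tpl <- entry_tpl + (plans$depth_mm[k] + depth_err) * u
    center_tpl <- tip_tpl + kit$tip_to_core_center_mm * u
    to_ref <- rt_compose(ph$true_ref, ph$true_cal)
    truth[[k]] <- list(
      needle_id = needle_ids[k], phantom_id = ph$phantom_id,
      entry = rt_apply(to_ref, pt3(entry_tpl, frame = "TEMPLATE")),
      tip = rt_apply(to_ref, pt3(tip_tpl, frame = "TEMPLATE")),
      center = rt_apply(to_ref, pt3(center_tpl, frame = "TEMPLATE")),
      direction = rt_apply(to_ref, dir3(u)))
  }
  truth_cores <- do.call(rbind, lapply(truth, function(tc) {
    data.frame(phantom_id = tc$phantom_id, needle_id = tc$needle_id,
               center_x_mm = tc$center$xyz[1], center_y_mm = tc$center$xyz[2],
               center_z_mm = tc$center$xyz[3],
               dir_x = unclass(tc$direction)[1], dir_y = unclass(tc$direction)[2],
               dir_z = unclass(tc$direction)[3],
               frame = "REFERENCE", stringsAsFactors = FALSE)
  }))

  # --- component 4: fiducial picks per calibrating observer -----------------
  set.seed(.child_seed(config$seed, 4L))
  cal_obs <- sprintf("C%d", seq_len(config$n_cal_observers))
  fp <- list()
  for (i in seq_len(n_ph)) {
    ph <- phantoms[[i]]
    for (ob in cal_obs) {
      for (j in seq_along(config$fiducials$positions)) {
        true_low <- rt_apply(ph$true_cal, config$fiducials$positions[[j]])
        noise_xy <- stats::rnorm(2) * nm$fiducial_pick_sigma_mm
        p <- true_low$xyz + c(noise_xy, 0)
        if (nm$quantize_slices) {
          p[3] <- quantize_to_slices(p[3], nm$lowfield_slice_mm)
        }
        fp[[length(fp) + 1L]] <- data.frame(
          phantom_id = ph$phantom_id, observer_id = ob,
          label = config$fiducials$labels[j],
          x_mm = p[1], y_mm = p[2], z_mm = p[3], frame = "LOWFIELD",
          stringsAsFactors = FALSE)
      }
    }
  }
  fiducial_picks <- do.call(rbind, fp)

  # --- component 5: ground-truth entry/tip picks ----------------------------
  set.seed(.child_seed(config$seed, 5L))
  gt_obs <- sprintf("G%d", seq_len(config$n_gt_observers))
  gp <- list()
  for (k in seq_len(n_needles)) {
    tc <- truth[[k]]
    vis <- !(tc$needle_id %in% config$invisible_needles)
    for (ob in gt_obs) {
      for (kind in c("entry", "tip")) {
        true_pt <- tc[[kind]]
        noise_xy <- stats::rnorm(2) * nm$observer_pick_sigma_mm
        p <- true_pt$xyz + c(noise_xy, 0)
        if (nm$quantize_slices) {
          p[3] <- quantize_to_slices(p[3], nm$reference_slice_mm)
        }
        gp[[length(gp) + 1L]] <- data.frame(
          phantom_id = tc$phantom_id, observer_id = ob,
          needle_id = tc$needle_id, point_kind = kind,
          x_mm = p[1], y_mm = p[2], z_mm = p[3], frame = "REFERENCE",
          visible = as.integer(kind == "tip" || vis),
          stringsAsFactors = FALSE)
      }
    }
  }
  gt_picks <- do.call(rbind, gp)

  # --- component 6: box-corner landmark picks in both frames ----------------
  set.seed(.child_seed(config$seed, 6L))
  lm <- list()
  for (i in seq_len(n_ph)) {
    ph <- phantoms[[i]]
    corners <- .box_corners(ph$spec)
    to_ref <- rt_compose(ph$true_ref, ph$true_cal)
    for (j in seq_len(nrow(corners))) {
      c_tpl <- pt3(corners[j, ], frame = "TEMPLATE")
      for (fr in c("LOWFIELD", "REFERENCE")) {
        true_pt <- if (fr == "LOWFIELD") rt_apply(ph$true_cal, c_tpl)
                   else rt_apply(to_ref, c_tpl)
        noise_xy <- stats::rnorm(2) * nm$observer_pick_sigma_mm
        p <- true_pt$xyz + c(noise_xy, 0)
        if (nm$quantize_slices) {
          sl <- if (fr == "LOWFIELD") nm$lowfield_slice_mm else nm$reference_slice_mm
          p[3] <- quantize_to_slices(p[3], sl)
        }
        lm[[length(lm) + 1L]] <- data.frame(
          phantom_id = ph$phantom_id, label = paste0("corner", j), frame = fr,
          x_mm = p[1], y_mm = p[2], z_mm = p[3], stringsAsFactors = FALSE)
      }
    }
  }
  landmarks <- do.call(rbind, lm)

  structure(list(config = config, phantoms = phantoms, plans = plans,
                 targets = targets, truth_cores = truth_cores,
                 fiducial_picks = fiducial_picks, gt_picks = gt_picks,
                 landmarks = landmarks, n_resampled = n_resampled),
            class = "biopsy_experiment")
}

#' @export
print.biopsy_experiment <- function(x, ...) {
  cat(sprintf("<biopsy_experiment> %d phantoms, %d needles, %d GT + %d calibrating observers, seed %d\n",
              length(x$phantoms), nrow(x$plans), x$config$n_gt_observers,
              x$config$n_cal_observers, x$config$seed))
  invisible(x)
}
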