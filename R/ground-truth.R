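# Ground-truth core determination: observer entry/tip picks on the reference
# (1.5T) scan are extrapolated to the core that was actually sampled,
# averaged across observers, and the reference frame is registered to the
# low-field frame via box-corner landmarks.

#' Construct an observer needle pick
#'
#' One observer's identification of a needle on the reference scan: the
#' entry point where the needle enters the volume and the cannula tip. A
#' needle whose entry point could not be visualized is recorded with
#' `visible_entry = FALSE` and excluded downstream with a logged reason,
#' never silently dropped.
#'
#' @param observer_id,needle_id Identifiers.
#' @param entry,tip [pt3()] points in the `REFERENCE` frame.
#' @param visible_entry Logical; was the entry point identifiable?
#' @return An object of class `"observer_pick"`.
#' @export
observer_pick <- function(observer_id, needle_id, entry, tip,
                          visible_entry = TRUE) {
  stopifnot(.is_pt3(entry), .is_pt3(tip), is.logical(visible_entry))
  if (entry$frame != "REFERENCE" || tip$frame != "REFERENCE") {
    stop("observer picks live in the REFERENCE frame", call. = FALSE)
  }
  if (visible_entry && sqrt(sum((entry$xyz - tip$xyz)^2)) < 1e-9) {
    stop("entry and tip picks coincide for needle ", needle_id, call. = FALSE)
  }
  structure(list(observer_id = as.character(observer_id),
                 needle_id = as.character(needle_id),
                 entry = entry, tip = tip,
                 visible_entry = isTRUE(visible_entry)),
            class = "observer_pick")
}

#' Extrapolate the sampled core from an entry/tip pick
#'
#' The cannula tip marks where the cannula stopped; the core that the fired
#' needle sampled lies further along the needle direction. With unit
#' direction \eqn{u = (tip - entry)/|tip - entry|}, the core center is
#' `tip + tip_to_core_center_mm * u` and the core is a segment of
#' `core_length_mm` centered there.
#'
#' @param pick An [observer_pick()] with a visible entry.
#' @param kit A [biopsy_kit()] supplying the extrapolation offsets.
#' @return An object of class `"ground_truth_core"`: fields `needle_id`,
#'   `center` ([pt3()]), `segment` ([seg3()]), `direction` ([dir3()]),
#'   `source_observers`.
#' @export
extrapolate_core <- function(pick, kit) {
  stopifnot(inherits(pick, "observer_pick"), inherits(kit, "biopsy_kit"))
  if (!pick$visible_entry) {
    stop("entry point not visible for needle ", pick$needle_id,
         ": pick must be excluded, not extrapolated", call. = FALSE)
  }
  v <- pick$tip$xyz - pick$entry$xyz
  if (sqrt(sum(v^2)) < 1e-9) {
    stop("entry and tip coincide: needle direction undefined", call. = FALSE)
  }
  u <- v / sqrt(sum(v^2))
  center <- pick$tip$xyz + kit$tip_to_core_center_mm * u
  half <- kit$core_length_mm / 2
  fr <- pick$tip$frame
  structure(list(needle_id = pick$needle_id,
                 center = pt3(center, frame = fr),
                 segment = seg3(pt3(center - half * u, frame = fr),
                                pt3(center + half * u, frame = fr)),
                 direction = dir3(u),
                 source_observers = pick$observer_id),
            class = "ground_truth_core")
}

#' Average ground-truth core across observers for one needle
#'
#' The consensus core center is the componentwise mean of the per-observer
#' extrapolated core centers; the consensus direction is the renormalized
#' mean of the per-observer unit directions, and the consensus segment is
#' rebuilt around the mean center with the kit's core length. Picks with an
#' invisible entry are skipped and recorded in the `"excluded_observers"`
#' attribute of the result.
#'
#' @param picks List of [observer_pick()] objects for a single needle.
#' @param kit A [biopsy_kit()].
#' @return A consensus `"ground_truth_core"`.
#' @export
average_ground_truth <- function(picks, kit) {
  stopifnot(is.list(picks), length(picks) >= 1L)
  ids <- unique(vapply(picks, `[[`, "", "needle_id"))
  if (length(ids) != 1L) {
    stop("picks for multiple needles supplied: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  usable <- Filter(function(p) p$visible_entry, picks)
  skipped <- vapply(Filter(function(p) !p$visible_entry, picks),
                    `[[`, "", "observer_id")
  if (length(usable) == 0L) {
    stop("no usable picks for needle ", ids,
         ": every observer flagged the entry as not visible", call. = FALSE)
  }
  cores <- lapply(usable, extrapolate_core, kit = kit)
  C <- do.call(rbind, lapply(cores, function(co) co$center$xyz))
  U <- do.call(rbind, lapply(cores, function(co) unclass(co$direction)))
  center <- colMeans(C)
  u <- colMeans(U)
  if (sqrt(sum(u^2)) < 1e-9) {
    stop("observer needle directions cancel out: cannot form a consensus core",
         call. = FALSE)
  }
  u <- u / sqrt(sum(u^2))
  half <- kit$core_length_mm / 2
  fr <- cores[[1L]]$center$frame
  out <- structure(list(needle_id = ids,
                        center = pt3(center, frame = fr),
                        segment = seg3(pt3(center - half * u, frame = fr),
                                       pt3(center + half * u, frame = fr)),
                        direction = dir3(u),
                        source_observers = vapply(usable, `[[`, "", "observer_id")),
                   class = "ground_truth_core")
  attr(out, "excluded_observers") <- skipped
  out
}

#' Interobserver variability of needle tip picks
#'
#' For every needle identified by two or more observers, the Euclidean
#' distance between the observers' tip picks is computed (tip coordinates
#' only; entry visibility does not matter here), and the per-needle
#' distances are summarized by mean, SD, min and max. With more than two
#' observers on a needle, the mean of all pairwise tip distances is used for
#' that needle.
#'
#' @param picks Either a list of [observer_pick()] objects or a pick table
#'   data frame in the on-disk dialect (columns `observer_id`, `needle_id`,
#'   `point_kind`, `x_mm`, `y_mm`, `z_mm`, `frame`, `visible`).
#' @return A list with `n_needles`, `mean`, `sd`, `min`, `max` (all mm) and
#'   `per_needle`, a data frame of needle-level tip distances.
#' @export
interobserver_pick_stats <- function(picks) {
  if (is.data.frame(picks)) picks <- .picks_from_table(picks)
  stopifnot(is.list(picks), all(vapply(picks, inherits, TRUE, "observer_pick")))
  needles <- split(picks, vapply(picks, `[[`, "", "needle_id"))
  rows <- lapply(needles, function(ps) {
    obs <- vapply(ps, `[[`, "", "observer_id")
    if (length(unique(obs)) < 2L) return(NULL)
    tips <- do.call(rbind, lapply(ps, function(p) p$tip$xyz))
    d <- as.numeric(stats::dist(tips))
    data.frame(needle_id = ps[[1L]]$needle_id, tip_distance_mm = mean(d))
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows) || nrow(rows) == 0L) {
    stop("no needle was picked by two or more observers", call. = FALSE)
  }
  d <- rows$tip_distance_mm
  list(n_needles = nrow(rows), mean = mean(d),
       sd = if (length(d) > 1L) stats::sd(d) else 0,
       min = min(d), max = max(d),
       per_needle = rows[order(rows$needle_id), , drop = FALSE])
}

#' Register the reference frame to the low-field frame from landmarks
#'
#' Global rigid registration from corresponding landmark picks (e.g. corners
#' of the phantom box identified in both scans), wrapping [fit_rigid()]. The
#' resulting transform maps `REFERENCE` coordinates into the `LOWFIELD`
#' frame so that ground-truth cores and planned cores can be compared.
#'
#' @param landmarks_ref List of [pt3()] in `REFERENCE`.
#' @param landmarks_low Corresponding list of [pt3()] in `LOWFIELD`.
#' @return A list with `transform` (`REFERENCE -> LOWFIELD`
#'   [rigid_transform()]) and `fre` (RMS residual, mm).
#' @export
register_frames <- function(landmarks_ref, landmarks_low) {
  ok_ref <- all(vapply(landmarks_ref, function(p) p$frame == "REFERENCE", TRUE))
  ok_low <- all(vapply(landmarks_low, function(p) p$frame == "LOWFIELD", TRUE))
  if (!ok_ref || !ok_low) {
    stop("landmarks_ref must be in REFERENCE and landmarks_low in LOWFIELD",
         call. = FALSE)
  }
  fit_rigid(landmarks_ref, landmarks_low)
}

# rebuild observer_pick objects from the on-disk pick table
.picks_from_table <- function(df) {
  need <- c("observer_id", "needle_id", "point_kind", "x_mm", "y_mm", "z_mm",
            "frame", "visible")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    .schema_error("pick table is missing column(s): ",
                  paste(miss, collapse = ", "))
  }
  keys <- unique(df[, c("observer_id", "needle_id")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$observer_id == keys$observer_id[i] &
              df$needle_id == keys$needle_id[i], ]
    e <- sub[sub$point_kind == "entry", ]
    t <- sub[sub$point_kind == "tip", ]
    if (nrow(e) != 1L || nrow(t) != 1L) {
      .schema_error("needle ", keys$needle_id[i], " / observer ",
                    keys$observer_id[i],
                    " must have exactly one entry and one tip pick")
    }
    out[[i]] <- observer_pick(keys$observer_id[i], keys$needle_id[i],
                              entry = pt3(e$x_mm, e$y_mm, e$z_mm, frame = e$frame),
                              tip = pt3(t$x_mm, t$y_mm, t$z_mm, frame = t$frame),
                              visible_entry = as.logical(e$visible) &&
                                as.logical(t$visible))
  }
  out
}
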