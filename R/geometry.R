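# 3-D geometry primitives in named coordinate frames. All lengths are mm,
# all frames right-handed, all coordinates continuous (no voxel indexing).

.FRAMES <- c("TEMPLATE", "LOWFIELD", "REFERENCE")

.check_frame <- function(frame) {
  if (!is.character(frame) || length(frame) != 1L || !frame %in% .FRAMES) {
    stop("'frame' must be one of ", paste(.FRAMES, collapse = ", "),
         " (got ", deparse(frame), ")", call. = FALSE)
  }
  frame
}

#' Construct a 3-D point in a named coordinate frame
#'
#' Points carry their coordinate frame (`"TEMPLATE"`, `"LOWFIELD"` or
#' `"REFERENCE"`) so that frame mismatches are caught at computation time
#' rather than silently producing nonsense distances. Coordinates are in mm.
#'
#' @param x Numeric scalar, or a numeric vector of length 3 giving all three
#'   coordinates (in which case `y` and `z` must be omitted).
#' @param y,z Numeric scalars (mm).
#' @param frame Coordinate frame identifier, one of `"TEMPLATE"`,
#'   `"LOWFIELD"`, `"REFERENCE"`.
#' @return An object of class `"pt3"` with fields `xyz` (numeric length 3)
#'   and `frame`.
#' @examples
#' p <- pt3(0, 3, 4, frame = "LOWFIELD")
#' q <- pt3(c(0, 0, 0), frame = "LOWFIELD")
#' pt_distance(p, q) # 5
#' @export
pt3 <- function(x, y = NULL, z = NULL, frame) {
  xyz <- if (is.null(y) && is.null(z)) as.numeric(x) else as.numeric(c(x, y, z))
  if (length(xyz) != 3L) {
    stop("a point needs exactly 3 coordinates, got ", length(xyz), call. = FALSE)
  }
  if (!all(is.finite(xyz))) stop("point coordinates must be finite", call. = FALSE)
  structure(list(xyz = xyz, frame = .check_frame(frame)), class = "pt3")
}

#' @export
print.pt3 <- function(x, ...) {
  cat(sprintf("<pt3 %s> (%.4f, %.4f, %.4f) mm\n",
              x$frame, x$xyz[1], x$xyz[2], x$xyz[3]))
  invisible(x)
}

.is_pt3 <- function(p) inherits(p, "pt3")

.same_frame <- function(p, q, what = "points") {
  if (p$frame != q$frame) {
    stop(what, " are in different frames: ", p$frame, " vs ", q$frame,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a unit direction vector
#'
#' The input vector is normalized to unit Euclidean length; a zero-norm input
#' is an error. Directions are dimensionless and frame-agnostic (they rotate
#' with transforms but do not translate).
#'
#' @param ux Numeric scalar, or numeric length-3 vector of components.
#' @param uy,uz Numeric scalars.
#' @return An object of class `"dir3"`: a unit numeric vector of length 3.
#' @examples
#' dir3(0, 0, 2) # normalized to (0, 0, 1)
#' @export
dir3 <- function(ux, uy = NULL, uz = NULL) {
  u <- if (is.null(uy) && is.null(uz)) as.numeric(ux) else as.numeric(c(ux, uy, uz))
  if (length(u) != 3L || !all(is.finite(u))) {
    stop("a direction needs 3 finite components", call. = FALSE)
  }
  n <- sqrt(sum(u^2))
  if (n < 1e-12) stop("zero-norm direction vector", call. = FALSE)
  structure(u / n, class = "dir3")
}

#' Construct a line segment between two points
#'
#' Both endpoints must lie in the same frame and be distinct; a biopsy core
#' is represented as the segment between its two ends.
#'
#' @param a,b Endpoints of class [pt3()] in the same frame.
#' @return An object of class `"seg3"` with fields `a`, `b`, `frame`.
#' @export
seg3 <- function(a, b) {
  stopifnot(.is_pt3(a), .is_pt3(b))
  .same_frame(a, b, "segment endpoints")
  if (sqrt(sum((a$xyz - b$xyz)^2)) < 1e-12) {
    stop("degenerate segment: endpoints coincide", call. = FALSE)
  }
  structure(list(a = a, b = b, frame = a$frame), class = "seg3")
}

#' Segment length (mm)
#' @param seg A [seg3()] segment.
#' @return Numeric length in mm.
#' @export
seg_length <- function(seg) {
  stopifnot(inherits(seg, "seg3"))
  sqrt(sum((seg$b$xyz - seg$a$xyz)^2))
}

#' Segment midpoint
#' @param seg A [seg3()] segment.
#' @return The midpoint as a [pt3()].
#' @export
seg_midpoint <- function(seg) {
  pt3((seg$a$xyz + seg$b$xyz) / 2, frame = seg$frame)
}

#' Segment direction (unit vector from a to b)
#' @param seg A [seg3()] segment.
#' @return A [dir3()] direction.
#' @export
seg_direction <- function(seg) dir3(seg$b$xyz - seg$a$xyz)

#' Euclidean distance between two points
#'
#' The straight-line distance
#' \eqn{\sqrt{(x_2-x_1)^2 + (y_2-y_1)^2 + (z_2-z_1)^2}} used for the
#' center-to-center error metric and for interobserver tip variability.
#'
#' @param p,q Points of class [pt3()] in the same frame.
#' @return Non-negative distance in mm.
#' @export
pt_distance <- function(p, q) {
  stopifnot(.is_pt3(p), .is_pt3(q))
  .same_frame(p, q)
  sqrt(sum((p$xyz - q$xyz)^2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Perpendicular distance from a point to an infinite line
#'
#' Computes \eqn{|\,\overline{M_0 M_1} \times s\,| / |s|} where \eqn{M_0} is
#' the point, \eqn{M_1} a point on the line and \eqn{s} the line's directing
#' vector. This is the headline "point to line" error metric: the shortest
#' perpendicular distance from a planned target to the ground-truth core
#' trajectory.
#'
#' @param p Query point ([pt3()]).
#' @param line_point Any point on the line ([pt3()], same frame as `p`).
#' @param dir Directing vector of the line ([dir3()]).
#' @return Non-negative distance in mm; zero iff `p` lies on the line.
#' @export
point_line_distance <- function(p, line_point, dir) {
  stopifnot(.is_pt3(p), .is_pt3(line_point), inherits(dir, "dir3"))
  .same_frame(p, line_point, "point and line")
  sqrt(sum(.cross3(p$xyz - line_point$xyz, unclass(dir))^2))
}

#' Distance from a point to a line segment
#'
#' Equals [point_line_distance()] when the foot of the perpendicular falls
#' within the segment, and the distance to the nearer endpoint otherwise.
#' This is the physically clamped variant of the point-to-line metric: a
#' biopsy core has finite extent, so distances beyond its ends are measured
#' to the end of the core.
#'
#' @param p Query point ([pt3()]).
#' @param seg Segment ([seg3()]) in the same frame.
#' @return Non-negative distance in mm.
#' @export
point_segment_distance <- function(p, seg) {
  stopifnot(.is_pt3(p), inherits(seg, "seg3"))
  .same_frame(p, seg$a, "point and segment")
  ab <- seg$b$xyz - seg$a$xyz
  t <- sum((p$xyz - seg$a$xyz) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((seg$a$xyz + t * ab - p$xyz)^2))
}

#' Construct a rigid transform between two frames
#'
#' A proper rigid transform (rotation + translation, no scaling or shear)
#' mapping coordinates from `from_frame` into `to_frame`:
#' \eqn{p' = R p + t}. The rotation must be orthonormal with determinant +1.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric length-3 translation (mm).
#' @param from_frame,to_frame Frame identifiers.
#' @return An object of class `"rigid_transform"`.
#' @export
rigid_transform <- function(rotation, translation, from_frame, to_frame) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation matrix is not orthonormal", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation matrix is not proper (det != +1): reflection or scaling present",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation,
                 from_frame = .check_frame(from_frame),
                 to_frame = .check_frame(to_frame)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform %s -> %s>\n", x$from_frame, x$to_frame))
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", paste(round(x$translation, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Identity rigid transform
#' @param from_frame,to_frame Frame identifiers (may differ: an identity
#'   relabelling between coincident frames).
#' @return A [rigid_transform()].
#' @export
rt_identity <- function(from_frame, to_frame = from_frame) {
  rigid_transform(diag(3), c(0, 0, 0), from_frame, to_frame)
}

#' Apply a rigid transform to a point, direction or segment
#'
#' @param t A [rigid_transform()].
#' @param x A [pt3()] (must be in `t$from_frame`), a [dir3()] (rotated only),
#'   or a [seg3()].
#' @return The transformed object, expressed in `t$to_frame`.
#' @export
rt_apply <- function(t, x) {
  stopifnot(inherits(t, "rigid_transform"))
  if (.is_pt3(x)) {
    if (x$frame != t$from_frame) {
      stop("transform expects frame ", t$from_frame, " but point is in ",
           x$frame, call. = FALSE)
    }
    return(pt3(drop(t$rotation %*% x$xyz) + t$translation, frame = t$to_frame))
  }
  if (inherits(x, "dir3")) {
    return(dir3(drop(t$rotation %*% unclass(x))))
  }
  if (inherits(x, "seg3")) {
    return(seg3(rt_apply(t, x$a), rt_apply(t, x$b)))
  }
  stop("cannot apply a rigid transform to an object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

# matrix form: M is n x 3 in from_frame; returns n x 3 in to_frame
.rt_apply_mat <- function(t, M) {
  sweep(M %*% t(t$rotation), 2, -t$translation)
}

#' Compose two rigid transforms
#'
#' `rt_compose(t2, t1)` is the transform applying `t1` first, then `t2`;
#' `t1$to_frame` must equal `t2$from_frame`.
#'
#' @param t2,t1 [rigid_transform()] objects.
#' @return The composed [rigid_transform()] from `t1$from_frame` to
#'   `t2$to_frame`.
#' @export
rt_compose <- function(t2, t1) {
  stopifnot(inherits(t2, "rigid_transform"), inherits(t1, "rigid_transform"))
  if (t1$to_frame != t2$from_frame) {
    stop("frame chain mismatch: first transform ends in ", t1$to_frame,
         " but second starts in ", t2$from_frame, call. = FALSE)
  }
  rigid_transform(t2$rotation %*% t1$rotation,
                  drop(t2$rotation %*% t1$translation) + t2$translation,
                  t1$from_frame, t2$to_frame)
}

#' Invert a rigid transform
#' @param t A [rigid_transform()].
#' @return The inverse [rigid_transform()] (frames swapped).
#' @export
rt_invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  rigid_transform(Rt, drop(-Rt %*% t$translation), t$to_frame, t$from_frame)
}

#' Serialize / deserialize a rigid transform to a JSON-ready list
#'
#' The serialized form is `{rotation: 9 numbers row-major, translation: 3
#' numbers, from_frame, to_frame}`, suitable for `jsonlite::toJSON()`.
#'
#' @param t A [rigid_transform()].
#' @return `rt_serialize`: a named list; `rt_deserialize`: the transform.
#' @export
rt_serialize <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  list(rotation = as.numeric(t(t$rotation)),
       translation = t$translation,
       from_frame = t$from_frame, to_frame = t$to_frame)
}

#' @rdname rt_serialize
#' @param x A list as produced by `rt_serialize` (e.g. parsed from JSON).
#' @export
rt_deserialize <- function(x) {
  rigid_transform(matrix(as.numeric(x$rotation), 3, 3, byrow = TRUE),
                  as.numeric(x$translation), x$from_frame, x$to_frame)
}

#' Least-squares rigid registration of two corresponding point sets
#'
#' Closed-form orthogonal Procrustes fit (SVD of the cross-covariance with
#' reflection correction, the Kabsch/Horn solution): finds the proper rigid
#' transform minimizing the sum of squared residuals
#' \eqn{\sum_i \| R\,src_i + t - dst_i \|^2}. This is the solver behind both
#' template fiducial calibration and reference-to-low-field landmark
#' registration.
#'
#' @param src,dst Lists of [pt3()] points in correspondence (same length,
#'   at least 3 pairs); `src` must not be collinear. All `src` points share
#'   one frame and all `dst` points another (or the same).
#' @return A list with components `transform` (the fitted
#'   [rigid_transform()] from the src frame to the dst frame) and `fre`
#'   (fiducial registration error: the root-mean-square residual, mm).
#' @examples
#' src <- list(pt3(0, 0, 0, frame = "TEMPLATE"), pt3(10, 0, 0, frame = "TEMPLATE"),
#'             pt3(0, 10, 0, frame = "TEMPLATE"), pt3(0, 0, 10, frame = "TEMPLATE"))
#' shift <- function(p) pt3(p$xyz + c(1, 2, 3), frame = "LOWFIELD")
#' fit <- fit_rigid(src, lapply(src, shift))
#' fit$fre # 0
#' @export
fit_rigid <- function(src, dst) {
  if (!is.list(src) || !is.list(dst) || length(src) != length(dst)) {
    stop("src and dst must be lists of points of equal length", call. = FALSE)
  }
  n <- length(src)
  if (n < 3L) {
    stop("rigid fit needs at least 3 point pairs, got ", n, call. = FALSE)
  }
  stopifnot(all(vapply(src, .is_pt3, TRUE)), all(vapply(dst, .is_pt3, TRUE)))
  from_frame <- src[[1L]]$frame
  to_frame <- dst[[1L]]$frame
  if (!all(vapply(src, function(p) p$frame == from_frame, TRUE)) ||
      !all(vapply(dst, function(p) p$frame == to_frame, TRUE))) {
    stop("all src points must share one frame and all dst points another",
         call. = FALSE)
  }
  S <- do.call(rbind, lapply(src, `[[`, "xyz"))
  D <- do.call(rbind, lapply(dst, `[[`, "xyz"))
  sc <- colMeans(S)
  dc <- colMeans(D)
  S0 <- sweep(S, 2, sc)
  D0 <- sweep(D, 2, dc)
  sv_src <- svd(S0)$d
  if (sv_src[2] < 1e-9 * max(sv_src[1], 1)) {
    stop("source points are collinear: rigid fit is underdetermined",
         call. = FALSE)
  }
  H <- crossprod(S0, D0)                      # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))            # reflection correction
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- dc - drop(R %*% sc)
  fit <- rigid_transform(R, tr, from_frame, to_frame)
  res <- .rt_apply_mat(fit, S) - D
  list(transform = fit, fre = sqrt(mean(rowSums(res^2))))
}

#' Radius of a sphere of given volume
#'
#' Converts a tumor volume in cm\eqn{^3} to the radius (mm) of the
#' equivalent sphere, \eqn{r = (3V/4\pi)^{1/3}}. The clinically significant
#' lesion volume of 0.5 cm\eqn{^3} corresponds to a radius of about 5 mm,
#' which is the accuracy acceptance bound used throughout.
#'
#' @param volume_cc Sphere volume in cm^3 (cc); must be positive.
#' @return Radius in mm.
#' @examples
#' sphere_radius_from_volume(0.5) # ~4.92 mm, i.e. about 5 mm
#' @export
sphere_radius_from_volume <- function(volume_cc) {
  if (!is.numeric(volume_cc) || any(!is.finite(volume_cc)) || any(volume_cc <= 0)) {
    stop("volume must be a positive finite number (cm^3)", call. = FALSE)
  }
  10 * (3 * volume_cc / (4 * pi))^(1 / 3)
}
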