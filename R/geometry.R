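# Pure 3D geometric primitives. Every primitive here is deterministic and
# has a brute-force or closed-form oracle in the test suite.

#' Construct an axis (infinite oriented line)
#'
#' An axis is a point plus a unit direction. Directions are normalized on
#' construction; a zero-length direction is an error.
#'
#' @param point 3D point on the line (mm).
#' @param direction 3D direction vector (any nonzero length; normalized).
#' @param orientation_note free-text note on the orientation convention,
#'   e.g. "points proximal".
#' @return Object of class `fm_axis` with fields `point`, `direction`
#'   (unit), `orientation_note`.
#' @export
fm_axis <- function(point, direction, orientation_note = "") {
  structure(
    list(point = as_point(point, "axis point"),
         direction = unitv(as_point(direction, "axis direction"),
                           "axis direction"),
         orientation_note = as.character(orientation_note)),
    class = "fm_axis")
}

#' @export
print.fm_axis <- function(x, ...) {
  cat(sprintf("<fm_axis> through (%.3f, %.3f, %.3f), direction (%.6f, %.6f, %.6f) %s\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3],
              if (nzchar(x$orientation_note)) paste0("[", x$orientation_note, "]") else ""))
  invisible(x)
}

#' Least-squares sphere fit
#'
#' Algebraic (linear) least-squares fit of a sphere to >= 5 points, solving
#' the normal equations of `|x - c|^2 = r^2` expanded in `(2c, r^2 - |c|^2)`.
#' Exact (to machine precision) for noise-free spherical samples; used to
#' locate the femoral head center.
#'
#' @param points n x 3 matrix (or list) of points, n >= 5, not coplanar.
#' @return Object of class `fm_sphere_fit`: `center`, `radius`,
#'   `rms_residual` (all mm).
#' @export
fit_sphere <- function(points) {
  pts <- as_point_matrix(points, min_n = 5L, what = "sphere fit points")
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  qa <- qr(A)
  if (qa$rank < 4L) {
    stop("degenerate sphere fit: points are coplanar or otherwise rank-deficient",
         call. = FALSE)
  }
  sol <- qr.coef(qa, b)
  center <- unname(sol[1:3])
  r2 <- sol[4L] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate sphere fit: non-positive squared radius", call. = FALSE)
  }
  radius <- sqrt(r2)
  d <- sqrt(rowSums(sweep(pts, 2L, center)^2))
  structure(list(center = center, radius = radius,
                 rms_residual = sqrt(mean((d - radius)^2))),
            class = "fm_sphere_fit")
}

#' Total-least-squares 3D line fit
#'
#' First principal direction of the centered point cloud, through the
#' centroid. The direction sign is chosen to point from the last input
#' point toward the first, so that proximal-to-distal ordered canal
#' centroids yield a proximally oriented axis.
#'
#' @param points n x 3 matrix (or list), n >= 2, not all identical.
#' @param orientation_note note stored on the returned axis.
#' @return `fm_axis`.
#' @export
fit_line <- function(points, orientation_note = "points from last input point toward first") {
  pts <- as_point_matrix(points, min_n = 2L, what = "line fit points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2L, ctr)
  if (max(abs(X)) < .fm_tol$degenerate) {
    stop("degenerate line fit: all points identical", call. = FALSE)
  }
  dir <- svd(X, nu = 0L)$v[, 1L]
  ref <- pts[1L, ] - pts[nrow(pts), ]
  if (sum(ref * dir) < 0) dir <- -dir
  fm_axis(ctr, dir, orientation_note)
}

#' Common-perpendicular distance between two lines
#'
#' Minimal distance between two (generally skew) lines and the mutually
#' closest points. This is the primitive behind the femur neck-shaft axis
#' offset: the offset is the length of the common perpendicular between
#' the neck axis and the proximal shaft axis.
#'
#' If the directions are parallel within `parallel_tol` (radians, compared
#' against the sine of the angle between the unit directions) the distance
#' returned is the perpendicular distance between the lines, the closest
#' points are reported at `a$point` and its projection onto `b`, and
#' `parallel_flag` is set.
#'
#' @param a,b `fm_axis` objects.
#' @param parallel_tol parallelism tolerance in radians.
#' @return Object of class `fm_skew_result`: `distance` (mm),
#'   `point_on_line1`, `point_on_line2`, `parallel_flag`.
#' @export
skew_distance <- function(a, b, parallel_tol = .fm_tol$parallel_rad) {
  stopifnot(inherits(a, "fm_axis"), inherits(b, "fm_axis"))
  d1 <- a$direction
  d2 <- b$direction
  w <- b$point - a$point
  cr <- cross3(d1, d2)
  sin_ang <- vnorm(cr)      # both directions are unit vectors
  if (sin_ang < parallel_tol) {
    p1 <- a$point
    p2 <- b$point + sum((p1 - b$point) * d2) * d2
    return(structure(list(distance = vnorm(p1 - p2),
                          point_on_line1 = p1, point_on_line2 = p2,
                          parallel_flag = TRUE),
                     class = "fm_skew_result"))
  }
  dd <- sum(d1 * d2)
  wd1 <- sum(w * d1)
  wd2 <- sum(w * d2)
  den <- 1 - dd^2
  s <- (wd1 - dd * wd2) / den
  t <- (dd * wd1 - wd2) / den
  p1 <- a$point + s * d1
  p2 <- b$point + t * d2
  structure(list(distance = vnorm(p1 - p2),
                 point_on_line1 = p1, point_on_line2 = p2,
                 parallel_flag = FALSE),
            class = "fm_skew_result")
}

#' Unsigned angle between two vectors, in degrees
#'
#' arccos of the clamped normalized dot product; range \[0, 180\].
#'
#' @param u,v nonzero 3D vectors.
#' @return angle in degrees.
#' @export
angle_between <- function(u, v) {
  u <- unitv(as_point(u, "vector u"), "vector u")
  v <- unitv(as_point(v, "vector v"), "vector v")
  rad2deg(acos(min(1, max(-1, sum(u * v)))))
}

#' Signed angle between vector projections in a plane
#'
#' Projects `u` and `v` onto the plane perpendicular to `plane_normal` and
#' returns the signed angle from `v` to `u`, sign by the right-hand rule
#' about `signed_about`. Range (-180, 180]. Used for femoral anteversion
#' (neck axis vs posterior condylar axis in the plane perpendicular to the
#' shaft axis).
#'
#' @param u,v 3D vectors, neither parallel to `plane_normal`.
#' @param plane_normal normal of the projection plane.
#' @param signed_about rotation reference for the sign; must be parallel
#'   (either sense) to `plane_normal`. Defaults to `plane_normal`.
#' @return signed angle in degrees.
#' @export
projected_angle <- function(u, v, plane_normal, signed_about = plane_normal) {
  n <- unitv(as_point(plane_normal, "plane normal"), "plane normal")
  sa <- unitv(as_point(signed_about, "sign reference"), "sign reference")
  u <- as_point(u, "vector u")
  v <- as_point(v, "vector v")
  up <- u - sum(u * n) * n
  vp <- v - sum(v * n) * n
  if (vnorm(up) < .fm_tol$degenerate || vnorm(vp) < .fm_tol$degenerate) {
    stop("degenerate projection: vector (near-)parallel to the plane normal",
         call. = FALSE)
  }
  cr <- cross3(vp, up)
  ang <- rad2deg(atan2(sum(cr * sa), sum(up * vp)))
  # atan2 yields (-180, 180]; -180 only from rounding of the antiparallel case
  if (ang <= -180) ang <- 180
  ang
}

#' Circumscribed circle of three points in 3D
#'
#' Radius and center of the unique circle through three non-collinear
#' points. The radius equals `|ab||bc||ac| / (4 area)`; the center is
#' solved from the perpendicular-bisector system and is equidistant from
#' the three points to machine precision. This carries the radius of
#' curvature of the femoral shaft: entry point, point of maximal deviation,
#' and distal canal point.
#'
#' @param p1,p2,p3 3D points (mm), triangle area > 1e-9 mm^2.
#' @return list `radius` (mm), `center` (3D point).
#' @export
circumradius <- function(p1, p2, p3) {
  p1 <- as_point(p1, "p1"); p2 <- as_point(p2, "p2"); p3 <- as_point(p3, "p3")
  a <- p2 - p1
  b <- p3 - p1
  n <- cross3(a, b)
  area <- vnorm(n) / 2
  if (area <= .fm_tol$area_mm2) {
    stop("collinear points: curvature unresolvable / radius effectively infinite",
         call. = FALSE)
  }
  # center x solves (x-p1).a = |a|^2/2 ; (x-p1).b = |b|^2/2 ; (x-p1).n = 0
  M <- rbind(a, b, n)
  rhs <- c(sum(a * a) / 2, sum(b * b) / 2, 0)
  center <- p1 + as.numeric(solve(M, rhs))
  list(radius = vnorm(center - p1), center = center)
}

#' Point of maximal perpendicular deviation from a chord
#'
#' Among an ordered set of points, find the one with the largest
#' perpendicular distance to the infinite line through `chord_start` and
#' `chord_end`. Ties are broken by the smallest index (relevant for noisy
#' or straight arcs).
#'
#' @param points n x 3 matrix (or list), n >= 3.
#' @param chord_start,chord_end distinct 3D points defining the chord.
#' @return list `index` (1-based), `point`, `deviation` (mm).
#' @export
max_deviation_point <- function(points, chord_start, chord_end) {
  pts <- as_point_matrix(points, min_n = 3L, what = "deviation points")
  s <- as_point(chord_start, "chord start")
  e <- as_point(chord_end, "chord end")
  u <- unitv(e - s, "chord")
  rel <- sweep(pts, 2L, s)
  # |rel x u| = perpendicular distance since u is unit
  cx <- rel[, 2L] * u[3L] - rel[, 3L] * u[2L]
  cy <- rel[, 3L] * u[1L] - rel[, 1L] * u[3L]
  cz <- rel[, 1L] * u[2L] - rel[, 2L] * u[1L]
  d <- sqrt(cx^2 + cy^2 + cz^2)
  i <- which.max(d)   # which.max returns the first maximum: smallest index
  list(index = i, point = pts[i, ], deviation = d[i])
}
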