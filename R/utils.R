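# Internal numeric helpers shared across the geometry, generator and
# measurement layers. All tolerances live in one place (fm_tolerances).

.fm_tol <- list(
  unit_dir        = 1e-9,  # tolerated deviation of |direction| from 1 in an axis
  parallel_rad    = 1e-9,  # sin(angle) below which two lines count as parallel
  area_mm2        = 1e-9,  # triangle area below which a circumcircle is undefined
  degenerate      = 1e-9,  # generic floor for projections / vector lengths
  curvature_cap_m = 100,   # reported radius for an effectively straight canal
  prox_window_mm  = 100    # chord-length window of the proximal shaft-axis fit
)

#' Numerical tolerances used by the package
#'
#' All hard-coded geometric tolerances are centralized here: the
#' parallel-line threshold for skew-distance computations, the collinearity
#' floor for circumcircle fitting, the cap applied to the radius of
#' curvature of an effectively straight canal, and the chord-length window
#' (mm) over which the proximal shaft axis is fitted.
#'
#' @return Named list of tolerance constants.
#' @export
fm_tolerances <- function() .fm_tol

# vector cross product, length-3 numeric
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v, what = "vector") {
  n <- vnorm(v)
  if (!is.finite(n) || n < .fm_tol$degenerate) {
    stop(sprintf("degenerate %s: length below %g", what, .fm_tol$degenerate),
         call. = FALSE)
  }
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

as_point <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x) || !all(is.finite(x))) {
    stop(sprintf("%s must be a finite 3D coordinate", what), call. = FALSE)
  }
  unname(x)
}

# Coerce a matrix / data.frame / list-of-points to an n x 3 numeric matrix.
as_point_matrix <- function(points, min_n = 1L, what = "points") {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, lapply(points, as.numeric))
  }
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) {
    stop(sprintf("%s must have 3 columns (x, y, z)", what), call. = FALSE)
  }
  if (nrow(pts) < min_n) {
    stop(sprintf("%s requires at least %d points, got %d", what, min_n,
                 nrow(pts)), call. = FALSE)
  }
  if (!all(is.finite(pts))) {
    stop(sprintf("%s contains non-finite coordinates", what), call. = FALSE)
  }
  dimnames(pts) <- NULL
  pts
}

# Rodrigues rotation of vector v about unit axis k by theta radians.
rotate_about <- function(v, k, theta) {
  k <- unitv(k, "rotation axis")
  v * cos(theta) + cross3(k, v) * sin(theta) + k * sum(k * v) * (1 - cos(theta))
}

# truncated-normal draws by rejection; bounds are generous (>= a few sd wide)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  stopifnot(lower < upper, lower <= mean, mean <= upper)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}
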