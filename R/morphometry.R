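# The measurement battery: eight scalar measures computed from a
# specimen's landmarks only — never from generator ground truth.

#' Estimate the femoral neck axis
#'
#' Sphere-fits the head surface points, appends the fitted head center to
#' the neck station centroids, and fits a total-least-squares line through
#' the set. The direction points from the lateral entry toward the head
#' center (medial).
#'
#' @param s `femur_specimen`.
#' @return `fm_axis` (direction toward the head).
#' @export
estimate_neck_axis <- function(s) {
  validate_specimen(s)
  head_fit <- fit_sphere(s$landmarks$head_surface)
  pts <- rbind(s$landmarks$neck_station_centroids, head_fit$center)
  ax <- fit_line(pts, orientation_note = "points medial, toward the head center")
  if (sum(ax$direction * (head_fit$center - pts[1L, ])) < 0) {
    ax$direction <- -ax$direction
  }
  attr(ax, "head_fit") <- head_fit
  ax
}

#' Estimate a femoral shaft axis
#'
#' Three variants, differing in how much of the femur defines the axis:
#' \describe{
#'   \item{proximal}{total-least-squares fit of the canal centroids within
#'     the first 100 mm of cumulative chord length (the operational
#'     proximal femur axis; reference for the offset, the proximal
#'     neck-shaft angle and anteversion).}
#'   \item{bow_apex}{line from the proximal-most canal centroid to the
#'     canal's point of maximal deviation from the entry-to-DICN chord
#'     (half-femur definition).}
#'   \item{dicn}{line from the proximal-most canal centroid to the distal
#'     intercondylar notch landmark (complete-femur definition).}
#' }
#' All variants are oriented to point proximal.
#'
#' @param s `femur_specimen`.
#' @param variant `"proximal"`, `"bow_apex"` or `"dicn"`.
#' @return `fm_axis`.
#' @export
estimate_shaft_axis <- function(s, variant = c("proximal", "bow_apex", "dicn")) {
  validate_specimen(s)
  variant <- match.arg(variant)
  canal <- s$landmarks$canal_centroids
  entry <- canal[1L, ]
  dicn <- landmark_point(s, "dicn")
  if (variant == "proximal") {
    return(shaft_axis_proximal_from_points(canal))
  }
  if (variant == "dicn") {
    return(fm_axis(entry, entry - dicn, "points proximal"))
  }
  apex <- max_deviation_point(canal, entry, dicn)
  if (apex$deviation <= .fm_tol$degenerate) {
    # straight shaft: the apex collapses onto the chord; the bow-apex and
    # complete-femur definitions coincide
    return(fm_axis(entry, entry - dicn, "points proximal (straight-shaft fallback)"))
  }
  fm_axis(entry, entry - apex$point, "points proximal")
}

#' Femur neck-shaft axis offset (FNSAO)
#'
#' Common-perpendicular distance between the neck axis and the proximal
#' shaft axis. These are skew lines in a normal femur; the neck axis
#' passes anterior to the shaft axis. Parallel axes are anatomically
#' impossible and signal corrupt input, so `parallel_flag` propagates as
#' an error.
#'
#' @param s `femur_specimen`.
#' @return list `fnsao_mm`, `closest_point_on_shaft` (3D point on the
#'   proximal shaft axis), `closest_point_on_neck`.
#' @export
measure_fnsao <- function(s) {
  neck <- estimate_neck_axis(s)
  shaft <- estimate_shaft_axis(s, "proximal")
  sk <- skew_distance(neck, shaft)
  if (sk$parallel_flag) {
    stop("neck and shaft axes are parallel: anatomically impossible, input is corrupt",
         call. = FALSE)
  }
  list(fnsao_mm = sk$distance,
       closest_point_on_shaft = sk$point_on_line2,
       closest_point_on_neck = sk$point_on_line1)
}

#' Greater trochanter tip to shaft-lag-screw-nail interface distance
#'
#' Distance measured along the proximal shaft axis between the orthogonal
#' projection of the greater trochanter tip and the neck/shaft axes'
#' closest-approach point (the anatomical analogue of the interface where
#' a cephalomedullary nail's lag screw crosses the nail). Positive when
#' the closest-approach point lies distal to the trochanter tip.
#'
#' @param s `femur_specimen`.
#' @return distance in mm.
#' @export
measure_gt_to_slsni <- function(s) {
  shaft <- estimate_shaft_axis(s, "proximal")
  fn <- measure_fnsao(s)
  dp <- shaft$direction
  gt <- landmark_point(s, "gt_tip")
  t_gt <- sum((gt - shaft$point) * dp)
  t_c <- sum((fn$closest_point_on_shaft - shaft$point) * dp)
  t_gt - t_c
}

#' Neck-shaft angle
#'
#' `180 -` the 3D angle between the neck direction (toward the head) and
#' the shaft direction (toward proximal) — an obtuse, inherently
#' anteversion-corrected ("true") neck-shaft angle. Reported for each of
#' the three shaft-axis variants.
#'
#' @param s `femur_specimen`.
#' @param variant shaft-axis variant, see [estimate_shaft_axis()].
#' @return angle in degrees.
#' @export
measure_nsa <- function(s, variant = c("proximal", "bow_apex", "dicn")) {
  variant <- match.arg(variant)
  neck <- estimate_neck_axis(s)
  shaft <- estimate_shaft_axis(s, variant)
  180 - angle_between(neck$direction, shaft$direction)
}

#' Femoral anteversion
#'
#' Signed angle, in the plane perpendicular to the proximal shaft axis,
#' from the posterior condylar axis (posterior-lateral to posterior-medial
#' condyle) to the neck axis. Anterior rotation is positive on both sides:
#' the sign reference is the proximal shaft direction for right femurs and
#' its opposite for left femurs (mirroring flips the frame's chirality).
#'
#' @param s `femur_specimen`.
#' @return signed angle in degrees (negative = retroversion).
#' @export
measure_anteversion <- function(s) {
  neck <- estimate_neck_axis(s)
  shaft <- estimate_shaft_axis(s, "proximal")
  cond <- landmark_point(s, "condyle_post_medial") -
          landmark_point(s, "condyle_post_lateral")
  ref <- if (s$side == "L") -shaft$direction else shaft$direction
  projected_angle(neck$direction, cond,
                  plane_normal = shaft$direction, signed_about = ref)
}

#' Femur neck axis length
#'
#' Distance from the lateral cortical entry of the neck axis to the head
#' apex, where the apex is the sphere-fitted head center displaced by the
#' fitted radius along the neck direction. This is the span a lag screw
#' must cover (lateral cortex to head apex).
#'
#' @param s `femur_specimen`.
#' @return length in mm.
#' @export
measure_neck_axis_length <- function(s) {
  neck <- estimate_neck_axis(s)
  head_fit <- attr(neck, "head_fit")
  apex <- head_fit$center + head_fit$radius * neck$direction
  vnorm(apex - landmark_point(s, "neck_lateral_entry"))
}

#' Intramedullary radius of curvature
#'
#' Radius (in meters) of the circle through the proximal-most canal
#' centroid, the canal's point of maximal perpendicular deviation from the
#' anatomical-axis chord (proximal entry to DICN), and the distal-most
#' canal centroid. Because the deviation is taken in 3D, the measure is
#' independent of the plane of maximal bow. An effectively straight canal
#' (collinear points, or a radius beyond the cap) is reported as the cap
#' value (100 m) with attribute `capped = TRUE` rather than an error, so
#' cohort statistics stay finite.
#'
#' @param s `femur_specimen`.
#' @return radius in meters (possibly capped).
#' @export
measure_radius_of_curvature <- function(s) {
  validate_specimen(s)
  canal <- s$landmarks$canal_centroids
  entry <- canal[1L, ]
  dicn <- landmark_point(s, "dicn")
  apex <- max_deviation_point(canal, entry, dicn)
  cap <- .fm_tol$curvature_cap_m
  r_m <- tryCatch(
    circumradius(entry, apex$point, canal[nrow(canal), ])$radius / 1000,
    error = function(e) cap)
  if (r_m >= cap) {
    return(structure(cap, capped = TRUE))
  }
  r_m
}

#' Compute all eight measures for one specimen
#'
#' Runs the full battery. A failure in any single measure poisons only its
#' field (reported as `NA`) and is collected in the `failures` attribute;
#' the remaining fields are still computed.
#'
#' @param s `femur_specimen`.
#' @return named list of class `measurement_record` with the eight measure
#'   fields; attribute `failures` is a named character vector of error
#'   messages (empty when everything succeeded).
#' @export
measure_all <- function(s) {
  validate_specimen(s)
  failures <- character(0)
  grab <- function(field, expr) {
    tryCatch(as.numeric(expr), error = function(e) {
      failures[[field]] <<- conditionMessage(e)
      NA_real_
    })
  }
  rec <- list(
    fnsao_mm = grab("fnsao_mm", measure_fnsao(s)$fnsao_mm),
    gt_to_slsni_mm = grab("gt_to_slsni_mm", measure_gt_to_slsni(s)),
    neck_axis_length_mm = grab("neck_axis_length_mm", measure_neck_axis_length(s)),
    nsa_proximal_deg = grab("nsa_proximal_deg", measure_nsa(s, "proximal")),
    nsa_bow_apex_deg = grab("nsa_bow_apex_deg", measure_nsa(s, "bow_apex")),
    nsa_dicn_deg = grab("nsa_dicn_deg", measure_nsa(s, "dicn")),
    radius_of_curvature_m = grab("radius_of_curvature_m",
                                 measure_radius_of_curvature(s)),
    anteversion_deg = grab("anteversion_deg", measure_anteversion(s)))
  structure(rec, class = "measurement_record", failures = failures)
}

#' Measure a list of specimens
#'
#' @param specimens list of `femur_specimen` objects (or a cohort as
#'   returned by [generate_cohort()], whose specimens are extracted).
#' @return data frame: `specimen_id, side, sex, age` plus the eight
#'   measure columns, one row per specimen.
#' @export
measure_cohort <- function(specimens) {
  specimens <- lapply(specimens, function(el) {
    if (inherits(el, "femur_specimen")) el else el$specimen
  })
  rows <- lapply(specimens, function(s) {
    rec <- measure_all(s)
    cbind(data.frame(specimen_id = s$specimen_id, side = s$side, sex = s$sex,
                     age = s$age, stringsAsFactors = FALSE),
          as.data.frame(unclass(rec)))
  })
  do.call(rbind, rows)
}
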