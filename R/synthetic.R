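# Forward model: parametric synthetic femur landmark sets with known
# ground truth, and cohort sampling from published population
# distributions. This is the desk-scale stand-in for CT-derived data.
#
# The geometry is built in the canonical right-femur frame (+X medial,
# +Y anterior, +Z proximal): a circular-arc intramedullary centerline
# bowing anteriorly in the sagittal plane, a neck axis leaving the shaft
# at the neck-shaft angle, rotated anteriorly by the anteversion, and
# displaced anteriorly off the shaft axis by the neck-shaft axis offset
# (FNSAO) along the common perpendicular, plus a spherical head.
#
# The proximal shaft reference axis is defined OPERATIONALLY: the same
# total-least-squares fit over the proximal 100 mm of canal centroids
# that the measurement stage uses. Building the neck relative to that
# operational axis (rather than the analytic arc tangent) is what makes
# the noise-free round trip exact: an arc tangent and a fitted secant
# differ by about s/(2R) radians (~2.4 degrees at R = 1.2 m).

# population distributions (cohort-level defaults): overall and by sex
.table1_distributions <- list(
  fnsao_mm              = list(mean = 6.1,   sd = 1.7),
  gt_to_slsni_mm        = list(mean = 40.3,  sd = 5.1),
  neck_axis_length_mm   = list(mean = 94.1,  sd = 7.4),
  nsa_proximal_deg      = list(mean = 126.3, sd = 5.4),
  radius_of_curvature_m = list(mean = 1.2,   sd = 0.3),
  anteversion_deg       = list(mean = 18.8,  sd = 9.2)
)

.table3_sex_distributions <- list(
  fnsao_mm              = list(M = list(mean = 6.2,   sd = 1.6),
                               F = list(mean = 5.9,   sd = 1.8)),
  gt_to_slsni_mm        = list(M = list(mean = 41.0,  sd = 5.9),
                               F = list(mean = 39.5,  sd = 3.8)),
  neck_axis_length_mm   = list(M = list(mean = 98.0,  sd = 6.6),
                               F = list(mean = 89.1,  sd = 5.0)),
  nsa_proximal_deg      = list(M = list(mean = 126.2, sd = 5.5),
                               F = list(mean = 126.5, sd = 5.4)),
  radius_of_curvature_m = list(M = list(mean = 1.2,   sd = 0.3),
                               F = list(mean = 1.1,   sd = 0.3)),
  anteversion_deg       = list(M = list(mean = 19.1,  sd = 9.6),
                               F = list(mean = 18.4,  sd = 8.8))
)

# physiologic hard bounds applied on top of mean +/- 4 sd truncation
.measure_hard_bounds <- list(
  fnsao_mm              = c(0, Inf),
  gt_to_slsni_mm        = c(0, Inf),
  neck_axis_length_mm   = c(0, Inf),
  nsa_proximal_deg      = c(91, 179),
  radius_of_curvature_m = c(0.5, Inf),
  anteversion_deg       = c(-89, 89)
)

#' Ground-truth parameters for one synthetic femur
#'
#' Encodes the generative twins of the measured quantities (neck-shaft
#' angle, anteversion, neck-shaft axis offset, trochanter-to-interface
#' distance, neck axis length, shaft bow radius) together with the
#' structural constants of the forward model.
#'
#' @param nsa_deg true neck-shaft angle in degrees, obtuse (90, 180),
#'   measured against the operational proximal axis.
#' @param anteversion_deg anteversion in degrees (negative = retroversion).
#' @param fnsao_mm neck-shaft axis offset, >= 0 mm (anterior).
#' @param gt_to_slsni_mm distance (mm) along the proximal axis from the
#'   greater-trochanter-tip projection to the axes' closest-approach point.
#' @param neck_axis_length_mm lateral cortical entry to head apex, mm;
#'   must exceed `head_center_from_n1_mm + head_radius_mm`.
#' @param bow_radius_mm radius of the circular-arc canal centerline, mm;
#'   must exceed `shaft_length_mm / pi` (arc shorter than a semicircle).
#' @param shaft_length_mm arc length of the modeled canal, mm.
#' @param head_radius_mm femoral head radius, mm.
#' @param gt_lateral_offset_mm,gt_proximal_offset_mm position of the
#'   greater trochanter tip relative to the canal entry (lateral, proximal).
#' @param head_center_from_n1_mm distance from the neck-axis foot of the
#'   common perpendicular to the head center, along the neck axis.
#' @param n_canal_stations,n_head_points,n_neck_stations landmark counts.
#' @param noise_sd_mm isotropic Gaussian landmark placement noise, mm.
#' @param side,sex,age specimen metadata.
#' @param seed optional integer seed for the landmark noise.
#' @return object of class `femur_parameters`.
#' @export
femur_parameters <- function(nsa_deg = 126.3, anteversion_deg = 18.8,
                             fnsao_mm = 6.1, gt_to_slsni_mm = 40.3,
                             neck_axis_length_mm = 94.1, bow_radius_mm = 1200,
                             shaft_length_mm = 400, head_radius_mm = 23,
                             gt_lateral_offset_mm = 10, gt_proximal_offset_mm = 8,
                             head_center_from_n1_mm = 55,
                             n_canal_stations = 41L, n_head_points = 20L,
                             n_neck_stations = 5L, noise_sd_mm = 0.5,
                             side = "R", sex = "unknown", age = NA_real_,
                             seed = NULL) {
  p <- structure(as.list(environment()), class = "femur_parameters")
  if (!(nsa_deg > 90 && nsa_deg < 180)) {
    stop("nsa_deg must lie in (90, 180)", call. = FALSE)
  }
  if (!(anteversion_deg > -90 && anteversion_deg < 90)) {
    stop("anteversion_deg must lie in (-90, 90)", call. = FALSE)
  }
  if (fnsao_mm < 0) stop("fnsao_mm must be >= 0", call. = FALSE)
  lengths <- c(gt_to_slsni_mm, neck_axis_length_mm, bow_radius_mm,
               shaft_length_mm, head_radius_mm, head_center_from_n1_mm)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("all lengths must be positive and finite", call. = FALSE)
  }
  if (bow_radius_mm <= shaft_length_mm / pi) {
    stop("bow_radius_mm must exceed shaft_length_mm / pi (arc below a semicircle)",
         call. = FALSE)
  }
  if (neck_axis_length_mm <= head_center_from_n1_mm + head_radius_mm) {
    stop("neck_axis_length_mm must exceed head_center_from_n1_mm + head_radius_mm",
         call. = FALSE)
  }
  if (noise_sd_mm < 0) stop("noise_sd_mm must be >= 0", call. = FALSE)
  if (!side %in% c("L", "R")) stop("side must be L or R", call. = FALSE)
  if (!sex %in% c("M", "F", "unknown")) stop("sex must be M, F or unknown", call. = FALSE)
  if (n_canal_stations < 10L || n_head_points < 5L || n_neck_stations < 3L) {
    stop("landmark counts below the minimum group cardinalities", call. = FALSE)
  }
  p
}

#' Circular-arc intramedullary centerline
#'
#' Stations equally spaced in arc length on a circle of radius
#' `bow_radius_mm` in the sagittal (Y-Z) plane, starting at the origin
#' with initial tangent (0, 0, -1) (pointing distal) and arc center at
#' (0, -R, 0), so the mid-arc bulges anterior (+Y) of the entry-to-end
#' chord — the anterior femoral bow.
#'
#' @param bow_radius_mm arc radius (mm), > `shaft_length_mm / pi`.
#' @param shaft_length_mm arc length (mm).
#' @param n_stations number of stations (>= 2).
#' @return `n_stations` x 3 matrix, ordered proximal to distal.
#' @export
generate_centerline <- function(bow_radius_mm, shaft_length_mm, n_stations) {
  if (n_stations < 2L) stop("n_stations must be >= 2", call. = FALSE)
  if (bow_radius_mm <= shaft_length_mm / pi) {
    stop("bow_radius_mm must exceed shaft_length_mm / pi", call. = FALSE)
  }
  s <- seq(0, shaft_length_mm, length.out = n_stations)
  th <- s / bow_radius_mm
  cbind(0, -bow_radius_mm + bow_radius_mm * cos(th), -bow_radius_mm * sin(th))
}

# deterministic near-uniform points on a sphere (golden-spiral lattice)
fibonacci_sphere <- function(n, center, radius) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  sweep(radius * cbind(r * cos(phi), r * sin(phi), z), 2L, center, `+`)
}

# TLS fit over the canal centroids whose cumulative chord length from the
# proximal entry is <= window mm; shared verbatim by the generator and the
# measurement stage so the operational axis definition is identical.
shaft_axis_proximal_from_points <- function(canal, window = .fm_tol$prox_window_mm) {
  cum <- c(0, cumsum(sqrt(rowSums((canal[-1L, , drop = FALSE] -
                                   canal[-nrow(canal), , drop = FALSE])^2))))
  sel <- canal[cum <= window, , drop = FALSE]
  if (nrow(sel) < 3L) {
    stop(sprintf("fewer than 3 canal centroids within the proximal %g mm window",
                 window), call. = FALSE)
  }
  fit_line(sel, orientation_note = "points proximal")
}

#' Generate one synthetic femur
#'
#' Builds the landmark set implied by a parameter record and returns it
#' with the matching ground-truth measurement record. Construction is in
#' the canonical right-femur frame; left femurs are mirrored across x = 0
#' before landmark noise is added. Noise-free specimens round-trip: every
#' measured quantity equals its encoded truth to ~1e-9 relative.
#'
#' @param p `femur_parameters`.
#' @param specimen_id id stored on the specimen and truth record.
#' @return list with elements `specimen` (`femur_specimen`) and `truth`
#'   (one-row data frame with metadata plus the eight measure fields).
#' @export
generate_specimen <- function(p, specimen_id = "synthetic") {
  stopifnot(inherits(p, "femur_parameters"))

  canal <- generate_centerline(p$bow_radius_mm, p$shaft_length_mm,
                               p$n_canal_stations)
  nsta <- nrow(canal)
  dicn <- canal[nsta, ]
  cpm <- dicn + c( 22, -15, 0)   # posterior medial condyle
  cpl <- dicn + c(-22, -15, 0)   # posterior lateral condyle

  ax <- shaft_axis_proximal_from_points(canal)
  dp <- ax$direction                       # unit, points proximal

  # greater trochanter tip, lateral (-X) and proximal of the canal entry
  G <- c(-p$gt_lateral_offset_mm, 0, p$gt_proximal_offset_mm)
  projG <- ax$point + sum((G - ax$point) * dp) * dp
  C <- projG - p$gt_to_slsni_mm * dp       # closest-approach point, distal of G

  # neck direction: tilt off the proximal axis toward medial by
  # beta = 180 - NSA, then rotate about the axis by the anteversion
  m <- unitv(c(1, 0, 0) - sum(c(1, 0, 0) * dp) * dp, "medial frame vector")
  f <- cross3(dp, m)                       # anterior frame vector
  beta <- deg2rad(180 - p$nsa_deg)
  d0 <- sin(beta) * m + cos(beta) * dp
  d_neck <- rotate_about(d0, dp, deg2rad(p$anteversion_deg))

  # common perpendicular, oriented anterior: the neck axis passes anterior
  # to the shaft axis by fnsao_mm
  u <- cross3(dp, d_neck)
  if (vnorm(u) < .fm_tol$degenerate) {
    stop("degenerate geometry: neck direction parallel to the shaft axis",
         call. = FALSE)
  }
  u <- u / vnorm(u)
  if (sum(u * f) < 0) u <- -u
  N1 <- C + p$fnsao_mm * u
  H <- N1 + p$head_center_from_n1_mm * d_neck
  Q <- N1 - (p$neck_axis_length_mm - p$head_center_from_n1_mm -
             p$head_radius_mm) * d_neck
  head_pts <- fibonacci_sphere(p$n_head_points, H, p$head_radius_mm)
  tseq <- seq(0, 1, length.out = p$n_neck_stations)
  neck_sta <- outer(1 - tseq, Q) + outer(tseq, H)

  # ground truth: encoded parameters; the two derived NSA variants follow
  # the measurement-stage axis definitions applied to the noise-free canal
  apex <- max_deviation_point(canal, canal[1L, ], dicn)
  dir_dicn <- unitv(canal[1L, ] - dicn, "entry-DICN chord")
  dir_bow <- if (apex$deviation > .fm_tol$degenerate) {
    unitv(canal[1L, ] - apex$point, "entry-apex chord")
  } else dir_dicn
  truth <- data.frame(
    specimen_id = specimen_id, side = p$side, sex = p$sex, age = p$age,
    fnsao_mm = p$fnsao_mm,
    gt_to_slsni_mm = p$gt_to_slsni_mm,
    neck_axis_length_mm = p$neck_axis_length_mm,
    nsa_proximal_deg = p$nsa_deg,
    nsa_bow_apex_deg = 180 - angle_between(d_neck, dir_bow),
    nsa_dicn_deg = 180 - angle_between(d_neck, dir_dicn),
    radius_of_curvature_m = p$bow_radius_mm / 1000,
    anteversion_deg = p$anteversion_deg,
    stringsAsFactors = FALSE)

  lm <- list(head_surface = head_pts,
             neck_station_centroids = neck_sta,
             canal_centroids = canal,
             gt_tip = matrix(G, nrow = 1L),
             neck_lateral_entry = matrix(Q, nrow = 1L),
             dicn = matrix(dicn, nrow = 1L),
             condyle_post_medial = matrix(cpm, nrow = 1L),
             condyle_post_lateral = matrix(cpl, nrow = 1L))
  if (p$side == "L") lm <- lapply(lm, function(mm) { mm[, 1L] <- -mm[, 1L]; mm })

  if (p$noise_sd_mm > 0) {
    if (!is.null(p$seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      }
      set.seed(as.integer(p$seed))
    }
    lm <- lapply(lm, function(mm) {
      mm + matrix(stats::rnorm(length(mm), 0, p$noise_sd_mm), nrow = nrow(mm))
    })
  }

  list(specimen = femur_specimen(specimen_id, p$side, p$sex, p$age, lm),
       truth = truth)
}

#' Cohort generation configuration
#'
#' Describes a synthetic population: per-measure truth distributions
#' (defaults are the published whole-cohort values; optionally
#' sex-stratified), demographic strata counts, landmark noise and seed.
#' Truths are drawn independently per measure from normals truncated at
#' mean +/- 4 sd (clipped further only by physiologic hard bounds, e.g.
#' offset >= 0 mm, curvature radius >= 0.5 m).
#'
#' @param n cohort size.
#' @param seed integer RNG seed; per-specimen noise seeds are derived from
#'   it, so any subset of the cohort is reproducible.
#' @param noise_sd_mm landmark noise passed to every specimen.
#' @param stratify_by_sex if `TRUE`, truths use the published sex-specific
#'   means/sds instead of the pooled ones.
#' @param measures optional list overriding the per-measure distributions;
#'   each element `list(mean =, sd =, lower =, upper =)` (bounds optional)
#'   named by the measure field, or for stratified configs
#'   `list(M = list(...), F = list(...))`.
#' @param sex_counts named vector `c(M =, F =)` summing to `n`; default
#'   scales the published 56/44 split.
#' @param side_counts named vector `c(L =, R =)` summing to `n`; default
#'   scales the published 49/51 split.
#' @param age list `mean, sd, lower, upper` for the age distribution.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n = 100L, seed = 1L, noise_sd_mm = 0.5,
                          stratify_by_sex = FALSE, measures = NULL,
                          sex_counts = NULL, side_counts = NULL,
                          age = list(mean = 35.2, sd = 13.5,
                                     lower = 18, upper = 75)) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0", call. = FALSE)
  if (is.null(sex_counts)) {
    m <- as.integer(round(0.56 * n)); sex_counts <- c(M = m, F = n - m)
  }
  if (is.null(side_counts)) {
    l <- as.integer(round(0.49 * n)); side_counts <- c(L = l, R = n - l)
  }
  sex_counts <- setNames(as.integer(sex_counts), names(sex_counts))
  side_counts <- setNames(as.integer(side_counts), names(side_counts))
  if (sum(sex_counts) != n || any(sex_counts < 0)) {
    stop("sex_counts must be non-negative and sum to n", call. = FALSE)
  }
  if (sum(side_counts) != n || any(side_counts < 0)) {
    stop("side_counts must be non-negative and sum to n", call. = FALSE)
  }
  base <- if (stratify_by_sex) .table3_sex_distributions else .table1_distributions
  if (!is.null(measures)) {
    for (nm in names(measures)) {
      if (!nm %in% names(base)) {
        stop(sprintf("unknown measure '%s' in measures", nm), call. = FALSE)
      }
      base[[nm]] <- utils::modifyList(base[[nm]], measures[[nm]])
    }
  }
  dists <- lapply(names(base), function(nm) {
    hard <- .measure_hard_bounds[[nm]]
    fill <- function(d) {
      if (d$sd < 0) stop("sd must be >= 0", call. = FALSE)
      if (is.null(d$lower)) d$lower <- max(d$mean - 4 * d$sd, hard[1L])
      if (is.null(d$upper)) d$upper <- min(d$mean + 4 * d$sd, hard[2L])
      if (!(d$lower <= d$mean && d$mean <= d$upper)) {
        stop(sprintf("truncation bounds for '%s' must bracket the mean", nm),
             call. = FALSE)
      }
      d
    }
    d <- base[[nm]]
    if (stratify_by_sex) lapply(d, fill) else fill(d)
  })
  names(dists) <- names(base)
  structure(list(n = n, seed = as.integer(seed), noise_sd_mm = noise_sd_mm,
                 stratify_by_sex = isTRUE(stratify_by_sex),
                 measures = dists, sex_counts = sex_counts,
                 side_counts = side_counts, age = age),
            class = "cohort_config")
}

#' Read a cohort configuration from JSON
#'
#' Keys mirror the [cohort_config()] arguments; absent keys fall back to
#' the defaults.
#'
#' @param path JSON file.
#' @return `cohort_config`.
#' @export
cohort_config_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- list()
  for (k in c("n", "seed", "noise_sd_mm", "stratify_by_sex", "age")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$sex_counts)) args$sex_counts <- unlist(raw$sex_counts)
  if (!is.null(raw$side_counts)) args$side_counts <- unlist(raw$side_counts)
  if (!is.null(raw$measures)) args$measures <- raw$measures
  do.call(cohort_config, args)
}

#' Generate a synthetic cohort
#'
#' Draws per-femur ground truths from the configured truncated-normal
#' distributions (sex-specific when stratified), assigns sexes and sides
#' per the configured strata counts, and builds each specimen with
#' [generate_specimen()]. Fully reproducible from the cohort seed; each
#' specimen receives a derived noise seed.
#'
#' For short necks the head-center offset along the neck axis is adapted
#' (`min(55, length - head_radius - 5)` mm) so every draw from the
#' population distribution yields valid geometry without asymmetric
#' truncation of the neck-length distribution.
#'
#' @param config `cohort_config`.
#' @return list of `n` elements, each `list(specimen =, truth =)`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  if (n == 0L) return(list())
  set.seed(config$seed)
  sexes <- sample(rep(c("M", "F"), times = config$sex_counts[c("M", "F")]))
  sides <- sample(rep(c("L", "R"), times = config$side_counts[c("L", "R")]))
  ages <- rtruncnorm(n, config$age$mean, config$age$sd,
                     config$age$lower, config$age$upper)
  draw_measure <- function(nm) {
    d <- config$measures[[nm]]
    if (config$stratify_by_sex) {
      out <- numeric(n)
      for (sx in c("M", "F")) {
        idx <- which(sexes == sx)
        out[idx] <- rtruncnorm(length(idx), d[[sx]]$mean, d[[sx]]$sd,
                               d[[sx]]$lower, d[[sx]]$upper)
      }
      out
    } else {
      rtruncnorm(n, d$mean, d$sd, d$lower, d$upper)
    }
  }
  truths <- lapply(names(config$measures), draw_measure)
  names(truths) <- names(config$measures)
  seeds <- sample.int(2147483646L, n)
  head_radius <- 23
  lapply(seq_len(n), function(i) {
    neck_len <- truths$neck_axis_length_mm[i]
    p <- femur_parameters(
      nsa_deg = truths$nsa_proximal_deg[i],
      anteversion_deg = truths$anteversion_deg[i],
      fnsao_mm = truths$fnsao_mm[i],
      gt_to_slsni_mm = truths$gt_to_slsni_mm[i],
      neck_axis_length_mm = neck_len,
      bow_radius_mm = truths$radius_of_curvature_m[i] * 1000,
      head_radius_mm = head_radius,
      head_center_from_n1_mm = min(55, neck_len - head_radius - 5),
      noise_sd_mm = config$noise_sd_mm,
      side = sides[i], sex = sexes[i], age = ages[i], seed = seeds[i])
    generate_specimen(p, specimen_id = sprintf("FEM%04d", i))
  })
}

#' Collect the ground-truth records of a cohort
#'
#' @param cohort output of [generate_cohort()].
#' @return data frame, one row per specimen.
#' @export
cohort_truth_table <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "truth"))
}

#' Write a cohort to disk
#'
#' One specimen JSON per femur (named by specimen id) plus a `truth.csv`
#' with the generating ground truths.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (el in cohort) {
    write_specimen(el$specimen,
                   file.path(dir, paste0(el$specimen$specimen_id, ".json")))
  }
  truth <- cohort_truth_table(cohort)
  if (!is.null(truth)) {
    write_measurements(truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}
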