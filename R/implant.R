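# Cephalomedullary nail catalog and anatomy-implant compatibility
# assessment. The bundled catalog transcribes the published parameters of
# two widely used nails (Gamma 3, InterTAN): neck-shaft angle options,
# radius-of-curvature options, lag-screw length range, built-in
# anteversion and trochanter-to-lag-screw-interface options.

#' Load an implant catalog
#'
#' Reads a JSON catalog of cephalomedullary nail specifications. With no
#' path, the catalog bundled with the package (two implants) is loaded.
#'
#' @param path optional path to a catalog JSON.
#' @return list of `implant_spec` objects.
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cmn_catalog.json", package = "femurmetrics",
                        mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(raw$implants) || length(raw$implants) == 0L) {
    stop("catalog schema error: no 'implants' array", call. = FALSE)
  }
  lapply(raw$implants, function(x) {
    for (k in c("name", "nsa_options_deg", "curvature_radii_m",
                "lag_screw_min_mm", "lag_screw_max_mm",
                "builtin_anteversion_deg")) {
      if (is.null(x[[k]])) {
        stop(sprintf("catalog schema error: implant lacks '%s'", k), call. = FALSE)
      }
    }
    if (length(x$nsa_options_deg) == 0L || length(x$curvature_radii_m) == 0L) {
      stop("catalog schema error: empty option list", call. = FALSE)
    }
    if (x$lag_screw_min_mm > x$lag_screw_max_mm) {
      stop("catalog schema error: lag_screw_min_mm > lag_screw_max_mm",
           call. = FALSE)
    }
    structure(list(
      name = x$name,
      nsa_options_deg = as.numeric(x$nsa_options_deg),
      curvature_radii_m = as.numeric(x$curvature_radii_m),
      lag_screw_min_mm = as.numeric(x$lag_screw_min_mm),
      lag_screw_max_mm = as.numeric(x$lag_screw_max_mm),
      builtin_anteversion_deg = as.numeric(x$builtin_anteversion_deg),
      gt_to_slsni_options_mm = as.numeric(x$gt_to_slsni_options_mm %||% numeric(0))),
      class = "implant_spec")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assess one femur against one implant
#'
#' Compares a complete measurement record with an implant specification:
#' \itemize{
#'   \item nearest neck-shaft angle option by absolute deviation (ties go
#'     to the smaller option); flag `NSA_OUT_OF_RANGE` beyond the
#'     threshold (default 5 degrees, half the typical option spacing);
#'   \item curvature mismatch when the femur radius is smaller than the
#'     smallest nail radius (a straighter nail than bone risks anterior
#'     cortex abutment), with the gap in meters;
#'   \item anteversion excess = femur anteversion minus the nail's
#'     built-in anteversion (flagged when positive);
#'   \item lag-screw coverage of the neck axis length;
#'   \item trochanter-to-interface deviation against the nearest catalog
#'     option (omitted when the implant lists none);
#'   \item `FNSAO_UNCOMPENSATED`, always: no current implant has a design
#'     parameter for the neck-shaft axis offset.
#' }
#' Missing record fields skip their comparison and add a
#' `MISSING_<field>` flag.
#'
#' @param m measurement record: `measurement_record`, one-row data frame
#'   or named list containing the eight measure fields.
#' @param imp `implant_spec`.
#' @param nsa_threshold_deg deviation (degrees) beyond which the NSA flag
#'   is raised.
#' @return object of class `compatibility_report`.
#' @export
assess <- function(m, imp, nsa_threshold_deg = 5) {
  stopifnot(inherits(imp, "implant_spec"))
  m <- as.list(m)
  val <- function(f) {
    v <- m[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) NA_real_ else as.numeric(v)
  }
  flags <- character(0)
  rep <- list(specimen_id = m$specimen_id %||% NA_character_,
              implant = imp$name)

  nsa <- val("nsa_proximal_deg")
  if (is.na(nsa)) {
    flags <- c(flags, "MISSING_nsa_proximal_deg")
    rep$nearest_nsa_option_deg <- NA_real_
    rep$nsa_deviation_deg <- NA_real_
  } else {
    dev <- abs(imp$nsa_options_deg - nsa)
    best <- sort(imp$nsa_options_deg[dev == min(dev)])[1L]  # tie: smaller option
    rep$nearest_nsa_option_deg <- best
    rep$nsa_deviation_deg <- abs(best - nsa)
    if (rep$nsa_deviation_deg > nsa_threshold_deg) {
      flags <- c(flags, "NSA_OUT_OF_RANGE")
    }
  }

  r <- val("radius_of_curvature_m")
  if (is.na(r)) {
    flags <- c(flags, "MISSING_radius_of_curvature_m")
    rep$curvature_mismatch <- NA
    rep$curvature_gap_m <- NA_real_
  } else {
    rmin <- min(imp$curvature_radii_m)
    rep$curvature_mismatch <- r < rmin
    rep$curvature_gap_m <- if (r < rmin) rmin - r else 0
    if (rep$curvature_mismatch) flags <- c(flags, "CURVATURE")
  }

  av <- val("anteversion_deg")
  if (is.na(av)) {
    flags <- c(flags, "MISSING_anteversion_deg")
    rep$anteversion_excess_deg <- NA_real_
  } else {
    rep$anteversion_excess_deg <- av - imp$builtin_anteversion_deg
    if (rep$anteversion_excess_deg > 0) flags <- c(flags, "ANTEVERSION_EXCESS")
  }

  len <- val("neck_axis_length_mm")
  if (is.na(len)) {
    flags <- c(flags, "MISSING_neck_axis_length_mm")
    rep$lag_length_covered <- NA
  } else {
    rep$lag_length_covered <- imp$lag_screw_min_mm <= len &&
                              len <= imp$lag_screw_max_mm
    if (!rep$lag_length_covered) flags <- c(flags, "LAG_LENGTH")
  }

  gt <- val("gt_to_slsni_mm")
  if (length(imp$gt_to_slsni_options_mm)) {
    if (is.na(gt)) {
      flags <- c(flags, "MISSING_gt_to_slsni_mm")
      rep$gt_slsni_deviation_mm <- NA_real_
    } else {
      rep$gt_slsni_deviation_mm <- min(abs(gt - imp$gt_to_slsni_options_mm))
    }
  } else {
    rep$gt_slsni_deviation_mm <- NA_real_   # implant does not specify options
  }

  # the offset has no implant counterpart at all: unconditional design gap
  flags <- c(flags, "FNSAO_UNCOMPENSATED")
  rep$overall_flags <- flags
  structure(rep, class = "compatibility_report")
}

#' @export
print.compatibility_report <- function(x, ...) {
  cat(sprintf("<compatibility_report> %s vs %s\n", x$specimen_id, x$implant))
  cat(sprintf("  nearest NSA option %.1f deg (deviation %.2f)\n",
              x$nearest_nsa_option_deg, x$nsa_deviation_deg))
  cat(sprintf("  curvature mismatch: %s (gap %.2f m)\n",
              x$curvature_mismatch, x$curvature_gap_m))
  cat(sprintf("  anteversion excess: %.2f deg; lag length covered: %s\n",
              x$anteversion_excess_deg, x$lag_length_covered))
  cat("  flags:", paste(x$overall_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten compatibility reports to a data frame
#'
#' @param reports list of `compatibility_report` objects (or a single one).
#' @return data frame, one row per report; flags collapsed with `;`.
#' @export
compat_report_table <- function(reports) {
  if (inherits(reports, "compatibility_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(specimen_id = r$specimen_id, implant = r$implant,
               nearest_nsa_option_deg = r$nearest_nsa_option_deg,
               nsa_deviation_deg = r$nsa_deviation_deg,
               curvature_mismatch = r$curvature_mismatch,
               curvature_gap_m = r$curvature_gap_m,
               anteversion_excess_deg = r$anteversion_excess_deg,
               lag_length_covered = r$lag_length_covered,
               gt_slsni_deviation_mm = r$gt_slsni_deviation_mm,
               overall_flags = paste(r$overall_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Cohort-level compatibility summary
#'
#' Assesses every record against one implant and rolls the reports up to
#' per-flag prevalences (proportions in \[0, 1\]) and mean deviations.
#'
#' @param records data frame of measurement records (one row per femur).
#' @param imp `implant_spec`.
#' @param nsa_threshold_deg passed to [assess()].
#' @return list: `implant`, `n`, `flag_prevalence` (named numeric),
#'   `mean_nsa_deviation_deg`, `mean_curvature_gap_m`,
#'   `mean_anteversion_excess_deg`, `mean_gt_slsni_deviation_mm`.
#' @export
cohort_compat_summary <- function(records, imp, nsa_threshold_deg = 5) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("cohort_compat_summary requires at least one record", call. = FALSE)
  }
  reports <- lapply(seq_len(nrow(records)),
                    function(i) assess(records[i, , drop = FALSE], imp,
                                       nsa_threshold_deg))
  all_flags <- c("NSA_OUT_OF_RANGE", "CURVATURE", "ANTEVERSION_EXCESS",
                 "LAG_LENGTH", "FNSAO_UNCOMPENSATED")
  prev <- vapply(all_flags, function(f) {
    mean(vapply(reports, function(r) f %in% r$overall_flags, logical(1)))
  }, numeric(1))
  num <- function(field) {
    v <- vapply(reports, function(r) r[[field]] %||% NA_real_, numeric(1))
    mean(v, na.rm = TRUE)
  }
  list(implant = imp$name, n = length(reports), flag_prevalence = prev,
       mean_nsa_deviation_deg = num("nsa_deviation_deg"),
       mean_curvature_gap_m = num("curvature_gap_m"),
       mean_anteversion_excess_deg = num("anteversion_excess_deg"),
       mean_gt_slsni_deviation_mm = num("gt_slsni_deviation_mm"))
}
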