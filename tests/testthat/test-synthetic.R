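# forward model: centerline geometry, specimen construction, cohorts

test_that("generate_centerline lies on the stated circle and bows anterior", {
  R <- 1200; L <- 400
  cl <- generate_centerline(R, L, 41)
  expect_equal(nrow(cl), 41L)
  expect_equal(cl[1, ], c(0, 0, 0), tolerance = 1e-12)
  expect_true(all(abs(cl[, 1]) < 1e-12))                       # sagittal plane
  d <- sqrt(rowSums(sweep(cl, 2, c(0, -R, 0))^2))
  expect_lt(max(abs(d - R)), 1e-9)                             # on the circle
  # equal arc spacing: chord lengths all equal
  gaps <- sqrt(rowSums((cl[-1, ] - cl[-41, ])^2))
  expect_lt(diff(range(gaps)), 1e-9)

  # mid-arc deviates anterior (+Y) of the entry-to-end chord
  md <- max_deviation_point(cl, cl[1, ], cl[41, ])
  chord_mid <- (cl[1, ] + cl[41, ]) / 2
  expect_gt(md$point[2], chord_mid[2])
  expect_equal(md$deviation, R * (1 - cos((L / R) / 2)), tolerance = 1e-3)

  # straight-shaft limit
  cl_straight <- generate_centerline(1e9, L, 41)
  md_s <- max_deviation_point(cl_straight, cl_straight[1, ], cl_straight[41, ])
  expect_lt(md_s$deviation, 1e-3)

  expect_error(generate_centerline(100, 400, 41), "semicircle|exceed")
})

test_that("published construction parameters round-trip through measurement", {
  p <- femur_parameters(nsa_deg = 126.3, anteversion_deg = 18.8,
                        fnsao_mm = 6.1, gt_to_slsni_mm = 40.3,
                        neck_axis_length_mm = 94.1, bow_radius_mm = 1200,
                        noise_sd_mm = 0)
  g <- generate_specimen(p)
  rec <- measure_all(g$specimen)
  expect_equal(rec$fnsao_mm, 6.1, tolerance = 1e-6)
  expect_equal(rec$gt_to_slsni_mm, 40.3, tolerance = 1e-6)
  expect_equal(rec$neck_axis_length_mm, 94.1, tolerance = 1e-6)
  expect_equal(rec$nsa_proximal_deg, 126.3, tolerance = 1e-6)
  expect_equal(rec$radius_of_curvature_m, 1.2, tolerance = 1e-6)
  expect_equal(rec$anteversion_deg, 18.8, tolerance = 1e-6)
  # derived variants echo the truth record
  expect_equal(rec$nsa_bow_apex_deg, g$truth$nsa_bow_apex_deg, tolerance = 1e-6)
  expect_equal(rec$nsa_dicn_deg, g$truth$nsa_dicn_deg, tolerance = 1e-6)
})

test_that("zero offset makes the axes intersect", {
  g <- generate_specimen(femur_parameters(fnsao_mm = 0, noise_sd_mm = 0))
  fn <- measure_fnsao(g$specimen)
  expect_equal(fn$fnsao_mm, 0, tolerance = 1e-9)
  expect_equal(fn$closest_point_on_shaft, fn$closest_point_on_neck,
               tolerance = 1e-9)
})

test_that("straight-shaft limit collapses the three NSA variants", {
  g <- generate_specimen(femur_parameters(anteversion_deg = 0,
                                          bow_radius_mm = 1e9,
                                          noise_sd_mm = 0))
  nsa <- vapply(c("proximal", "bow_apex", "dicn"),
                function(v) measure_nsa(g$specimen, v), numeric(1))
  expect_lt(max(nsa) - min(nsa), 1e-3)
  # and the shaft-axis variants are mutually parallel
  axes <- lapply(c("proximal", "bow_apex", "dicn"),
                 function(v) estimate_shaft_axis(g$specimen, v))
  expect_lt(angle_between(axes[[1]]$direction, axes[[2]]$direction), 1e-4)
  expect_lt(angle_between(axes[[1]]$direction, axes[[3]]$direction), 1e-4)
})

test_that("bowed shaft separates the NSA variants pairwise", {
  g <- generate_specimen(femur_parameters(bow_radius_mm = 1200,
                                          noise_sd_mm = 0))
  axes <- lapply(c("proximal", "bow_apex", "dicn"),
                 function(v) estimate_shaft_axis(g$specimen, v))
  expect_gt(angle_between(axes[[1]]$direction, axes[[2]]$direction), 0.1)
  expect_gt(angle_between(axes[[1]]$direction, axes[[3]]$direction), 0.1)
  expect_gt(angle_between(axes[[2]]$direction, axes[[3]]$direction), 0.1)
})

test_that("specimen generation is deterministic given a seed", {
  p <- femur_parameters(noise_sd_mm = 0.5, seed = 99L)
  g1 <- generate_specimen(p)
  g2 <- generate_specimen(p)
  for (grp in names(g1$specimen$landmarks)) {
    expect_identical(g1$specimen$landmarks[[grp]], g2$specimen$landmarks[[grp]])
  }
})

test_that("parameter invariants are enforced", {
  expect_error(femur_parameters(nsa_deg = 85), "90")
  expect_error(femur_parameters(fnsao_mm = -1), "fnsao")
  expect_error(femur_parameters(bow_radius_mm = 120, shaft_length_mm = 400),
               "semicircle|exceed")
  expect_error(femur_parameters(neck_axis_length_mm = 70), "exceed")
  expect_error(femur_parameters(noise_sd_mm = -0.1), "noise")
})

test_that("default cohort reproduces the demographic strata", {
  cfg <- cohort_config(seed = 17)
  expect_identical(cfg$n, 100L)
  expect_identical(unname(cfg$sex_counts[c("M", "F")]), c(56L, 44L))
  expect_identical(unname(cfg$side_counts[c("L", "R")]), c(49L, 51L))
  coh <- generate_cohort(cfg)
  expect_length(coh, 100L)
  truth <- cohort_truth_table(coh)
  expect_identical(sum(truth$sex == "M"), 56L)
  expect_identical(sum(truth$side == "L"), 49L)
  expect_true(all(truth$age >= 18 & truth$age <= 75))
})

test_that("empty cohort and seed reproducibility", {
  expect_identical(generate_cohort(cohort_config(n = 0)), list())
  c1 <- generate_cohort(cohort_config(n = 5, seed = 11))
  c2 <- generate_cohort(cohort_config(n = 5, seed = 11))
  for (i in 1:5) {
    for (grp in names(c1[[i]]$specimen$landmarks)) {
      expect_identical(c1[[i]]$specimen$landmarks[[grp]],
                       c2[[i]]$specimen$landmarks[[grp]])
    }
  }
})

test_that("cohort truths are drawn independently: age uncorrelated with offset", {
  set.seed(301)
  coh <- generate_cohort(cohort_config(n = 100, seed = 23))
  meas <- measure_cohort(coh)
  expect_lt(abs(cor(meas$age, meas$fnsao_mm)), 0.2)
})

test_that("sex-stratified cohorts use the per-sex neck-length distributions", {
  coh <- generate_cohort(cohort_config(n = 100, seed = 5, noise_sd_mm = 0,
                                       stratify_by_sex = TRUE))
  truth <- cohort_truth_table(coh)
  m <- truth$neck_axis_length_mm[truth$sex == "M"]
  f <- truth$neck_axis_length_mm[truth$sex == "F"]
  # 3 standard errors around the stratum means
  expect_lt(abs(mean(m) - 98.0), 3 * 6.6 / sqrt(length(m)))
  expect_lt(abs(mean(f) - 89.1), 3 * 5.0 / sqrt(length(f)))
})

test_that("cohort config validates counts and JSON round trip works", {
  expect_error(cohort_config(n = 10, sex_counts = c(M = 5, F = 6)), "sum to n")
  expect_error(cohort_config(n = 10, side_counts = c(L = -1, R = 11)),
               "non-negative")
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n = 12, seed = 3, noise_sd_mm = 0.1,
                            sex_counts = list(M = 6, F = 6),
                            side_counts = list(L = 6, R = 6)),
                       f, auto_unbox = TRUE)
  cfg <- cohort_config_from_json(f)
  expect_identical(cfg$n, 12L)
  expect_equal(cfg$noise_sd_mm, 0.1)
  expect_identical(unname(cfg$sex_counts[["M"]]), 6L)
})
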