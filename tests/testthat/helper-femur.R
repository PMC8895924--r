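# shared fixtures and independent oracles, built in code at test time

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# random rigid transform: proper rotation (via QR of a Gaussian matrix)
# plus translation
random_rigid <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 50))
}

apply_rigid_axis <- function(ax, rig) {
  fm_axis(as.numeric(rig$R %*% ax$point + rig$t),
          as.numeric(rig$R %*% ax$direction), ax$orientation_note)
}

apply_rigid_specimen <- function(s, rig) {
  lm <- lapply(s$landmarks, function(m) {
    sweep(m %*% t(rig$R), 2, rig$t, `+`)
  })
  femur_specimen(s$specimen_id, s$side, s$sex, s$age, lm)
}

# brute-force oracle for the minimal distance between two lines:
# evaluate |a(s) - b(t)| on a grid of line parameters and take the minimum;
# optional refinement passes re-grid around the coarse minimum (still pure
# grid search, no closed form)
grid_line_distance <- function(a, b, half_range = 40, n = 2000, passes = 1) {
  w <- b$point - a$point
  dd <- sum(a$direction * b$direction)
  wd1 <- sum(w * a$direction)
  wd2 <- sum(w * b$direction)
  eval_grid <- function(s, t) {
    # |a(s)-b(t)|^2 = |w|^2 + s^2 + t^2 - 2 s t (d1.d2) - 2 s (w.d1) + 2 t (w.d2)
    outer(s^2 - 2 * s * wd1, t^2 + 2 * t * wd2, `+`) - 2 * dd * outer(s, t)
  }
  cs <- 0; ct <- 0; hr <- half_range
  for (p in seq_len(passes)) {
    s <- seq(cs - hr, cs + hr, length.out = n)
    t <- seq(ct - hr, ct + hr, length.out = n)
    d2 <- eval_grid(s, t)
    idx <- arrayInd(which.min(d2), dim(d2))
    cs <- s[idx[1]]; ct <- t[idx[2]]
    best <- d2[idx]
    hr <- 2 * (s[2] - s[1])
  }
  sqrt(max(0, best + sum(w * w)))
}

# a valid random parameter set bounded away from sign changes and
# degeneracies, so relative round-trip tolerances are meaningful
random_params <- function(noise = 0, side = sample(c("L", "R"), 1)) {
  neck_len <- runif(1, 82, 112)
  femur_parameters(
    nsa_deg = runif(1, 110, 142),
    anteversion_deg = runif(1, 4, 35),
    fnsao_mm = runif(1, 1.5, 12),
    gt_to_slsni_mm = runif(1, 26, 54),
    neck_axis_length_mm = neck_len,
    bow_radius_mm = runif(1, 700, 2500),
    head_center_from_n1_mm = min(55, neck_len - 23 - 5),
    noise_sd_mm = noise,
    side = side)
}

measurement_vector <- function(rec) {
  unlist(rec[measurement_fields()])
}
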