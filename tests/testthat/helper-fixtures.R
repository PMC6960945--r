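# Shared fixtures and small oracles used across the test files.

# deterministic random rotation matrix via QR (oracle-independent of the
# package's own constructors)
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# componentwise cross product (brute-force oracle for skew())
cross_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize_oracle <- function(v) v / sqrt(sum(v^2))

deg2rad_oracle <- function(x) x * pi / 180

# angle between two vectors in degrees
vec_angle_deg <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# geodesic distance between two rotations in degrees
rot_angle_deg <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

# small fast two-link fixture (short, coarse but kinematically consistent)
short_sim <- function(duration = 6, seed = 42, sigma_acc = 14.8e-3,
                      sigma_gyro = 1.5e-3, ...) {
  cfg <- sim_config(duration = duration, sample_rate = 100, seed = seed,
                    sigma_acc = sigma_acc, sigma_gyro = sigma_gyro, ...)
  tr <- simulate_truth(cfg)
  list(cfg = cfg, truth = tr, imu = synthesize_imu(tr))
}
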