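# Two-link / n-link spherical-joint motion simulator.
#
# Each link carries one strapdown IMU. Link orientations follow smooth
# sum-of-sinusoid angular-velocity profiles (differentiable analytically, so
# the rigid-body constraint can be checked without numerical differentiation
# error). The first joint's center translates along an analytic trajectory;
# subsequent joint centers follow from the rigid links. Sensor accelerations
# are derived so that the shared-joint-center acceleration constraint holds
# exactly on the truth: for a link anchored at joint J with sensor-to-joint
# vector p (sensor frame),
#   r_sensor = r_J - R p  =>  a_sensor^S = R^T rdd_J - (skew(wdot)+skew(w)^2) p.

DEFAULT_P <- list(
  # measured sensor-to-joint-center vectors of the rigid two-link rig (m)
  p_i = c(0.498, -0.001, -0.031),
  p_j = c(0.512, 0.001, -0.027),
  # extra defaults for longer chains
  p_mid_next = c(-0.488, 0.004, -0.021),
  p_tail_prev = c(0.495, -0.003, -0.029)
)

#' Simulation configuration for spherical-joint chain motion
#'
#' Builds the full parameter set for [simulate_truth()] / [simulate_chain()]:
#' per-link angular-velocity profiles (sums of incommensurate sinusoids), an
#' analytic joint-center trajectory, sensor-to-joint geometry, noise levels
#' and the random seed. Each link's orientation follows bounded Z-Y-X Euler
#' angle oscillations about a home pose -- the mean-reverting motion of a
#' hand-excited rig, which keeps the joint pitch away from the Euler
#' degeneracy at +/- 90 degrees -- with angular rates of roughly 1-2 rad/s.
#' The angular velocity and acceleration are derived analytically from the
#' Euler rates, so the simulated truth is exact (no numerical integration or
#' differentiation anywhere). Defaults yield mean external accelerations of
#' 1-3 m/s^2; sensor noise defaults are accelerometer 14.8e-3 m/s^2 and
#' gyroscope 1.5e-3 rad/s (1-sigma, per axis). The joint-center translation
#' supplies most of the external acceleration (zero-mean in the body frame);
#' rotation amplitudes are yaw-dominant so each sensor's vertical axis stays
#' within ~20 degrees of the inertial vertical, as when the rig is swung by
#' hand, and the joint pitch stays well inside the +/- 90 degree Euler
#' envelope.
#'
#' @param duration Trial length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed; fixes the sinusoid profiles and the measurement
#'   noise, making the simulation fully reproducible.
#' @param n_links Number of rigid links (>= 2); `n_links` - 1 spherical joints.
#' @param gravity Gravitational acceleration (m/s^2).
#' @param angle_amp Length-3 total oscillation amplitudes (rad) of each
#'   link's yaw, pitch and roll about its home pose.
#' @param angle_freq_range Frequency band (Hz) of the orientation sinusoids.
#' @param n_sinusoids Sinusoids per Euler angle in each link's profile.
#' @param joint_amp Per-axis amplitude scale (m) of the first joint-center
#'   trajectory.
#' @param joint_freq_range Frequency band (Hz) of the joint trajectory.
#' @param sigma_acc,sigma_gyro Accelerometer (m/s^2) and gyroscope (rad/s)
#'   white-noise standard deviations.
#' @param p_next,p_prev Optional lists of sensor-to-joint-center vectors (m):
#'   `p_next[[k]]` points from link k's sensor to joint k (k < n_links),
#'   `p_prev[[k]]` from link k's sensor to joint k-1 (k > 1). Joint k couples
#'   `p_next[[k]]` and `p_prev[[k + 1]]`. Defaults are the measured vectors of
#'   the two-link rig, extended with generic values for longer chains.
#' @param static If `TRUE`, zero all motion (rate profiles and joint
#'   trajectory); links stay at their initial orientations.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 180, sample_rate = 100, seed = 1L,
                       n_links = 2L, gravity = 9.81,
                       angle_amp = c(0.7, 0.25, 0.25),
                       angle_freq_range = c(0.15, 0.8), n_sinusoids = 4L,
                       joint_amp = 0.4, joint_freq_range = c(0.3, 0.8),
                       sigma_acc = 14.8e-3, sigma_gyro = 1.5e-3,
                       p_next = NULL, p_prev = NULL, static = FALSE) {
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(sample_rate) ||
      sample_rate <= 0 || sigma_acc < 0 || sigma_gyro < 0) {
    imu_stop("invalid simulation config: need duration > 0, sample_rate > 0, sigmas >= 0",
             "imujoint_bad_config")
  }
  n_links <- as.integer(n_links)
  if (n_links < 2L) imu_stop("a chain needs at least 2 links", "imujoint_bad_config")

  if (is.null(p_next)) {
    p_next <- vector("list", n_links)
    p_next[[1L]] <- DEFAULT_P$p_i
    if (n_links > 2L) for (k in 2L:(n_links - 1L)) p_next[[k]] <- DEFAULT_P$p_mid_next
  }
  if (is.null(p_prev)) {
    p_prev <- vector("list", n_links)
    p_prev[[2L]] <- DEFAULT_P$p_j
    if (n_links > 2L) for (k in 3L:n_links) p_prev[[k]] <- DEFAULT_P$p_tail_prev
  }
  for (k in seq_len(n_links)) {
    if (k < n_links) check_vec3(p_next[[k]], sprintf("p_next[[%d]]", k))
    if (k > 1L) check_vec3(p_prev[[k]], sprintf("p_prev[[%d]]", k))
  }

  amp0 <- if (isTRUE(static)) c(0, 0, 0) else rep_len(angle_amp, 3L)
  jamp0 <- if (isTRUE(static)) 0 else joint_amp
  cfg <- with_seed(seed, {
    profiles <- lapply(seq_len(n_links), function(k) {
      sin_profile(3L, n_sinusoids, amp0, angle_freq_range)
    })
    joint_traj <- sin_profile(3L, 3L, jamp0, joint_freq_range)
    list(profiles = profiles, joint_traj = joint_traj)
  })

  # home poses: successive links roughly opposed (as two rods extending from
  # a shared joint), with small pitch offsets
  home <- lapply(seq_len(n_links), function(k) {
    c(deg2rad(170) * (k - 1L), deg2rad(4) * (k - 1L), 0)
  })

  structure(list(
    duration = duration, sample_rate = sample_rate, dt = 1 / sample_rate,
    seed = as.integer(seed), n_links = n_links, gravity = gravity,
    sigma_acc = sigma_acc, sigma_gyro = sigma_gyro,
    p_next = p_next, p_prev = p_prev,
    profiles = cfg$profiles, joint_traj = cfg$joint_traj, home = home,
    static = isTRUE(static)
  ), class = "sim_config")
}

# Draw a sum-of-sinusoids profile: per axis, n_sin components with random
# frequencies in `freq_range`, random phases, and amplitudes scaled so the
# per-axis amplitude sum is ~amp (drawn in [0.7, 1.3] * amp); `amp` may be a
# length-n_axes vector.
sin_profile <- function(n_axes, n_sin, amp, freq_range) {
  freq <- matrix(stats::runif(n_axes * n_sin, freq_range[1L], freq_range[2L]),
                 n_axes, n_sin)
  phase <- matrix(stats::runif(n_axes * n_sin, 0, 2 * pi), n_axes, n_sin)
  w <- matrix(stats::runif(n_axes * n_sin, 0.5, 1), n_axes, n_sin)
  scale <- amp * stats::runif(n_axes, 0.7, 1.3)
  ampm <- w / rowSums(w) * scale
  ampm[!is.finite(ampm)] <- 0
  list(amp = ampm, freq = freq, phase = phase)
}

# Evaluate a sinusoid profile and/or its derivatives on a time grid.
# order 0: f(t); 1: f'(t); 2: f''(t). Returns length(t) x n_axes matrix.
eval_profile <- function(prof, t, order = 0L) {
  n_axes <- nrow(prof$amp)
  out <- matrix(0, length(t), n_axes)
  for (a in seq_len(n_axes)) {
    w <- 2 * pi * prof$freq[a, ]
    arg <- outer(t, w) + rep(prof$phase[a, ], each = length(t))
    base <- switch(as.character(order),
      "0" = sin(arg),
      "1" = sweep(cos(arg), 2L, w, `*`),
      "2" = -sweep(sin(arg), 2L, w^2, `*`))
    out[, a] <- base %*% prof$amp[a, ]
  }
  out
}

# Body angular velocity and acceleration from Z-Y-X Euler angle trajectories
# (exact kinematics). For R = Rz(psi) Ry(th) Rx(phi):
#   wx = phi' - psi' sin(th)
#   wy = th' cos(phi) + psi' cos(th) sin(phi)
#   wz = psi' cos(th) cos(phi) - th' sin(phi)
# and wdot by direct differentiation. Inputs are Nx3 matrices of the angles
# (psi, th, phi) and their first/second time derivatives.
euler_body_rates <- function(ang, d1, d2) {
  psi1 <- d1[, 1L]; th1 <- d1[, 2L]; phi1 <- d1[, 3L]
  psi2 <- d2[, 1L]; th2 <- d2[, 2L]; phi2 <- d2[, 3L]
  st <- sin(ang[, 2L]); ct <- cos(ang[, 2L])
  sp <- sin(ang[, 3L]); cp <- cos(ang[, 3L])
  omega <- cbind(phi1 - psi1 * st,
                 th1 * cp + psi1 * ct * sp,
                 psi1 * ct * cp - th1 * sp)
  omega_dot <- cbind(
    phi2 - psi2 * st - psi1 * th1 * ct,
    th2 * cp - th1 * phi1 * sp + psi2 * ct * sp +
      psi1 * (-th1 * st * sp + phi1 * ct * cp),
    psi2 * ct * cp + psi1 * (-th1 * st * cp - phi1 * ct * sp) -
      th2 * sp - th1 * phi1 * cp)
  list(omega = omega, omega_dot = omega_dot)
}

#' Simulate ground-truth chain motion
#'
#' Evaluates every link's analytic orientation trajectory, derives the exact
#' body angular velocity and acceleration from the Euler rates, propagates
#' the joint-center acceleration down the chain, and derives each sensor's
#' external acceleration so the spherical-joint constraint holds exactly on
#' the truth. Everything entering the truth is analytic, not numerical.
#'
#' @param n_links Number of links (>= 2).
#' @param cfg A [sim_config()]; defaults to `sim_config(n_links = n_links)`.
#' @return A list of class `chain_truth` with elements `time`, `links` (per
#'   link: `R` 3x3xN orientation array, `omega`, `omega_dot`, `acc` as Nx3
#'   matrices in the sensor frame), `joints` (per joint: coupled links,
#'   p-vectors, true joint Euler angles Nx3, inertial joint-center
#'   acceleration `joint_acc`), and `config`.
#' @export
simulate_chain <- function(n_links = 2L, cfg = sim_config(n_links = n_links)) {
  n_links <- as.integer(n_links)
  if (n_links < 2L) imu_stop("n_links must be >= 2", "imujoint_bad_config")
  if (cfg$n_links != n_links) {
    imu_stop("cfg$n_links does not match n_links", "imujoint_bad_config")
  }
  N <- max(2L, round(cfg$duration * cfg$sample_rate))
  times <- (seq_len(N) - 1L) * cfg$dt

  links <- vector("list", n_links)
  for (k in seq_len(n_links)) {
    prof <- cfg$profiles[[k]]
    ang <- eval_profile(prof, times, 0L)
    ang <- sweep(ang, 2L, cfg$home[[k]], `+`)
    rates <- euler_body_rates(ang, eval_profile(prof, times, 1L),
                              eval_profile(prof, times, 2L))
    R <- array(NA_real_, c(3L, 3L, N))
    for (t in seq_len(N)) {
      R[, , t] <- dcm_from_euler_zyx(ang[t, 1L], ang[t, 2L], ang[t, 3L])
    }
    links[[k]] <- list(R = R, omega = rates$omega, omega_dot = rates$omega_dot,
                       euler = ang)
  }

  # inertial acceleration of joint 1 (analytic), then sensor accelerations and
  # joint-center propagation along the chain
  rdd_J <- eval_profile(cfg$joint_traj, times, 2L)  # N x 3, joint 1
  joints <- vector("list", n_links - 1L)
  for (k in seq_len(n_links)) {
    lk <- links[[k]]
    anchor_p <- if (k == 1L) cfg$p_next[[1L]] else cfg$p_prev[[k]]
    acc <- matrix(NA_real_, N, 3L)
    rdd_next <- if (k < n_links) matrix(NA_real_, N, 3L) else NULL
    for (t in seq_len(N)) {
      R <- lk$R[, , t]
      K <- skew(lk$omega_dot[t, ]) + skew(lk$omega[t, ]) %*% skew(lk$omega[t, ])
      acc[t, ] <- crossprod(R, rdd_J[t, ]) - K %*% anchor_p
      if (k < n_links) {
        # joint k acceleration: anchor joint plus rigid-link term (zero for
        # link 1, whose anchor is joint 1 itself)
        rdd_next[t, ] <- rdd_J[t, ] + R %*% (K %*% (cfg$p_next[[k]] - anchor_p))
      }
    }
    links[[k]]$acc <- acc
    if (k < n_links) {
      joints[[k]] <- list(link_a = k, link_b = k + 1L,
                          p_a = cfg$p_next[[k]], p_b = cfg$p_prev[[k + 1L]],
                          joint_acc = rdd_J)
      rdd_J <- rdd_next
    }
  }

  # true joint angles
  for (k in seq_len(n_links - 1L)) {
    Ra <- links[[k]]$R; Rb <- links[[k + 1L]]$R
    eul <- matrix(NA_real_, N, 3L, dimnames = list(NULL, c("alpha", "beta", "gamma")))
    for (t in seq_len(N)) {
      eul[t, ] <- euler_zyx_fast(crossprod(Ra[, , t], Rb[, , t]))
    }
    joints[[k]]$euler <- eul
  }

  structure(list(time = times, n_links = n_links, links = links,
                 joints = joints, config = cfg),
            class = "chain_truth")
}

#' Simulate ground-truth two-link motion
#'
#' Convenience wrapper around [simulate_chain()] for the canonical two-link,
#' one-joint system.
#'
#' @param cfg A [sim_config()] with `n_links = 2`.
#' @return A `chain_truth` object; see [simulate_chain()].
#' @export
simulate_truth <- function(cfg = sim_config()) {
  simulate_chain(cfg$n_links, cfg)
}

# Fast Z-Y-X Euler extraction without validity checks (internal hot path).
euler_zyx_fast <- function(R) {
  sb <- min(1, max(-1, -R[3L, 1L]))
  if (sqrt(R[3L, 2L]^2 + R[3L, 3L]^2) < 1e-7) {
    return(c(atan2(-R[1L, 2L], R[2L, 2L]), asin(sb), 0))
  }
  c(atan2(R[2L, 1L], R[1L, 1L]), asin(sb), atan2(R[3L, 2L], R[3L, 3L]))
}

#' Maximum spherical-joint constraint residual of a simulated truth
#'
#' For every joint and sample, evaluates the difference between the inertial
#' joint-center acceleration computed from each of the two coupled links
#' (using the analytic angular accelerations); returns the maximum norm per
#' joint. On a consistent truth this is at numerical round-off level.
#'
#' @param truth A `chain_truth`.
#' @return Numeric vector, one residual (m/s^2) per joint.
#' @export
constraint_residual <- function(truth) {
  vapply(truth$joints, function(jt) {
    la <- truth$links[[jt$link_a]]; lb <- truth$links[[jt$link_b]]
    N <- length(truth$time)
    worst <- 0
    for (t in seq_len(N)) {
      Ka <- skew(la$omega_dot[t, ]) + skew(la$omega[t, ]) %*% skew(la$omega[t, ])
      Kb <- skew(lb$omega_dot[t, ]) + skew(lb$omega[t, ]) %*% skew(lb$omega[t, ])
      ra <- la$R[, , t] %*% (la$acc[t, ] + Ka %*% jt$p_a)
      rb <- lb$R[, , t] %*% (lb$acc[t, ] + Kb %*% jt$p_b)
      worst <- max(worst, vnorm(ra - rb))
    }
    worst
  }, numeric(1))
}

#' Synthesize noisy IMU signals from a simulated truth
#'
#' Applies the sensor models: the gyroscope reads the true angular rate plus
#' white Gaussian noise, and the accelerometer reads gravity along the
#' attitude vector plus the external acceleration plus white Gaussian noise,
#' all in the sensor frame.
#'
#' @param truth A `chain_truth` from [simulate_chain()].
#' @param cfg Simulation config (defaults to the one stored in `truth`).
#' @param seed Seed for the noise draws; defaults to `cfg$seed` (offset
#'   internally so noise is independent of the motion-profile draws).
#' @return A list of `imu_series` data frames, one per link, with columns
#'   `t, gx, gy, gz, ax, ay, az` (s, rad/s, m/s^2).
#' @export
synthesize_imu <- function(truth, cfg = truth$config, seed = cfg$seed) {
  N <- length(truth$time)
  with_seed(seed * 7L + 13L, {
    lapply(seq_len(truth$n_links), function(k) {
      lk <- truth$links[[k]]
      Zs <- t(lk$R[3L, , ])                      # N x 3 attitude vector rows
      yg <- lk$omega + matrix(stats::rnorm(3L * N, sd = cfg$sigma_gyro), N, 3L)
      ya <- cfg$gravity * Zs + lk$acc +
        matrix(stats::rnorm(3L * N, sd = cfg$sigma_acc), N, 3L)
      imu_series(truth$time, yg, ya)
    })
  })
}

#' Construct an IMU series
#'
#' @param time Sample times (s), uniformly spaced.
#' @param gyro Nx3 angular rates (rad/s).
#' @param acc Nx3 specific forces (m/s^2).
#' @return A data frame of class `imu_series` with columns
#'   `t, gx, gy, gz, ax, ay, az`.
#' @export
imu_series <- function(time, gyro, acc) {
  gyro <- as.matrix(gyro); acc <- as.matrix(acc)
  if (length(time) != nrow(gyro) || length(time) != nrow(acc) ||
      ncol(gyro) != 3L || ncol(acc) != 3L) {
    imu_stop("time, gyro and acc must have matching lengths (Nx3)", "imujoint_bad_input")
  }
  if (length(time) >= 3L) {
    dts <- diff(time)
    if (max(abs(dts - dts[1L])) > 1e-9) {
      imu_stop("imu_series requires uniform sampling", "imujoint_bad_input")
    }
  }
  structure(data.frame(t = time,
                       gx = gyro[, 1L], gy = gyro[, 2L], gz = gyro[, 3L],
                       ax = acc[, 1L], ay = acc[, 2L], az = acc[, 3L]),
            class = c("imu_series", "data.frame"))
}

#' Add a constant gyroscope bias to an IMU series
#'
#' Utility for drift studies: real gyroscopes carry a slowly varying bias that
#' white-noise models omit; injecting a constant bias reproduces the
#' characteristic unbounded heading drift of uncorrected strapdown
#' integration.
#'
#' @param series An `imu_series`.
#' @param bias Length-3 bias vector (rad/s).
#' @return The series with `bias` added to the gyroscope columns.
#' @export
add_gyro_bias <- function(series, bias) {
  bias <- check_vec3(bias)
  series$gx <- series$gx + bias[1L]
  series$gy <- series$gy + bias[2L]
  series$gz <- series$gz + bias[3L]
  series
}

imu_gyro <- function(series) cbind(series$gx, series$gy, series$gz)
imu_acc <- function(series) cbind(series$ax, series$ay, series$az)
imu_dt <- function(series) {
  if (nrow(series) < 2L) imu_stop("series too short", "imujoint_bad_input")
  series$t[2L] - series$t[1L]
}
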