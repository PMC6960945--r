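# Heading Kalman filter with a spherical-joint acceleration constraint in
# place of magnetometer measurements — the core of the method.
#
# The state is the heading vector X (inertial x axis written in sensor
# coordinates). Both links' headings are predicted by strapdown integration;
# only the second link's heading is corrected, using two scalar equations
# obtained by projecting the shared joint-center acceleration onto the first
# link's heading axes. The first link's heading is free to drift: the joint
# angle (relative orientation) stays driftless because the correction keeps
# link j's heading consistent with link i's.

#' Initialize a heading filter state
#'
#' If no heading is supplied, the sensor x axis is projected orthogonal to
#' the attitude vector; the absolute heading of the chain's base link is
#' unobservable by design, so an arbitrary-but-consistent start is fine.
#'
#' @param z Unit attitude vector of the same link.
#' @param x Optional initial heading vector (sensor frame); any non-zero
#'   vector not parallel to `z`.
#' @param sigma0_deg Initial 1-sigma heading uncertainty (degrees).
#' @return A list with `X` (unit heading vector) and `P` (3x3 covariance).
#' @export
heading_init <- function(z, x = NULL, sigma0_deg = 10) {
  z <- normalize(check_vec3(z))
  if (is.null(x)) {
    x <- if (abs(z[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  x <- check_vec3(x)
  x <- x - sum(x * z) * z
  list(X = normalize(x), P = deg2rad(sigma0_deg)^2 * diag(3))
}

#' Heading filter prediction (strapdown)
#'
#' Rotates the heading vector by the exact per-step rotation
#' `exp(-dt * skew(y_g))` (first-order equivalent to the transition matrix
#' `I - dt*skew(y_g)`) and propagates the covariance with gyro-driven process
#' noise `dt^q * sigma_g^2 * skew(X) skew(X)^T`.
#'
#' @param state Heading state (see [heading_init()]).
#' @param y_g Gyroscope sample (rad/s).
#' @param dt Step size (s).
#' @param sigma_g Gyroscope noise standard deviation (rad/s).
#' @param q_dt_power Exponent of `dt` in the process noise (2 = discrete
#'   white noise, default; 1 = PSD convention).
#' @return Updated (a priori) heading state.
#' @export
heading_predict <- function(state, y_g, dt, sigma_g, q_dt_power = 2) {
  Phi <- rotvec_matrix(-dt * check_vec3(y_g))
  X <- normalize(Phi %*% state$X)
  Sx <- skew(X)
  Q <- dt^q_dt_power * sigma_g^2 * (Sx %*% t(Sx))
  P <- symmetrize(Phi %*% state$P %*% t(Phi) + Q)
  list(X = as.numeric(X), P = P)
}

#' Measurable joint-center acceleration of one link
#'
#' `C = y_a + (skew(y_gdot) + skew(y_g)^2) %*% p`: the joint-center
#' acceleration (gravity included) expressed in the sensor frame, computed
#' from that link's IMU signals and its sensor-to-joint-center vector.
#'
#' @param y_a Accelerometer sample (m/s^2).
#' @param y_g Gyroscope sample (rad/s).
#' @param y_gdot Angular acceleration (rad/s^2), from
#'   [differentiate_gyro()] or an analytic source.
#' @param p Sensor-to-joint-center vector (m, sensor frame).
#' @return Length-3 numeric vector (m/s^2).
#' @export
constraint_vector <- function(y_a, y_g, y_gdot, p) {
  y_a <- check_vec3(y_a); y_g <- check_vec3(y_g)
  y_gdot <- check_vec3(y_gdot); p <- check_vec3(p)
  as.numeric(y_a + (skew(y_gdot) + skew(y_g) %*% skew(y_g)) %*% p)
}

#' Numerical differentiation of the gyroscope signal
#'
#' Central differences at interior samples, first-order one-sided at the two
#' endpoints.
#'
#' @param series An `imu_series` (>= 3 samples, uniform rate).
#' @return An Nx3 matrix of angular accelerations (rad/s^2).
#' @export
differentiate_gyro <- function(series) {
  N <- nrow(series)
  if (is.null(N) || N < 3L) {
    imu_stop("differentiate_gyro needs at least 3 samples", "imujoint_bad_input")
  }
  dt <- imu_dt(series)
  G <- imu_gyro(series)
  D <- matrix(NA_real_, N, 3L)
  D[2L:(N - 1L), ] <- (G[3L:N, ] - G[1L:(N - 2L), ]) / (2 * dt)
  D[1L, ] <- (G[2L, ] - G[1L, ]) / dt
  D[N, ] <- (G[N, ] - G[N - 1L, ]) / dt
  D
}

# lambda matrices of the constraint error model: the error of C is
# eps = n_A + lambda1 n_G + lambda2 ndot_G with
# lambda1 = skew(p) skew(y_g) - 2 skew(y_g) skew(p), lambda2 = -skew(p).
constraint_lambdas <- function(y_g, p) {
  Sp <- skew(p); Sg <- skew(y_g)
  list(l1 = Sp %*% Sg - 2 * Sg %*% Sp, l2 = -Sp)
}

#' Constraint measurement (z, H) for the heading update
#'
#' Projects the joint-center acceleration seen by link i onto link i's
#' predicted heading axes (giving the 2-vector `z`) and forms the matching
#' observation matrix from link j's quantities:
#' `z = (C_i . X_i^-, C_i . (skew(Z_i^+) X_i^-))`,
#' `H = rbind(C_j^T, C_j^T skew(Z_j^+))`.
#'
#' @param C_i,C_j Joint-center accelerations per link
#'   (see [constraint_vector()]).
#' @param Z_i,Z_j A posteriori attitude vectors.
#' @param X_i Link i's current (predicted) heading vector.
#' @return A list with `z` (length 2) and `H` (2x3).
#' @export
constraint_measurement <- function(C_i, C_j, Z_i, Z_j, X_i) {
  z <- c(sum(C_i * X_i), sum(C_i * cross3(Z_i, X_i)))
  H <- rbind(C_j, as.numeric(crossprod(skew(Z_j), C_j)))
  dimnames(H) <- NULL
  list(z = z, H = H)
}

#' Constraint measurement-noise covariance M
#'
#' Assembles the 2x2 covariance of the constraint measurement error from the
#' sensor noise levels and the a posteriori attitude covariances. The error
#' of each link's joint-center acceleration is
#' `eps = n_A + lambda1 n_G + lambda2 ndot_G`, giving
#' `E(eps eps^T) = sigma_a^2 I + sigma_g^2 l1 l1^T + sigma_gdot^2 l2 l2^T`;
#' attitude errors enter through quadratic forms in `P_Z`. Products of error
#' terms are neglected (first-order model).
#'
#' @param C_i,C_j Joint-center accelerations.
#' @param Z_i,Z_j A posteriori attitude vectors.
#' @param X_i,X_j A priori heading vectors of links i and j.
#' @param P_Zi,P_Zj A posteriori attitude covariances.
#' @param y_gi,y_gj Gyroscope samples (rad/s).
#' @param p_i,p_j Sensor-to-joint-center vectors (m).
#' @param sigma_a,sigma_g,sigma_gdot Noise standard deviations of the
#'   accelerometer (m/s^2), gyroscope (rad/s) and differentiated gyroscope
#'   (rad/s^2).
#' @param gdot_lambda Which lambda matrix multiplies the
#'   differentiated-gyro noise term: `"lambda2"` (consistent with the error
#'   decomposition, default) or `"lambda1"`.
#' @return A symmetric PSD 2x2 matrix ((m/s^2)^2).
#' @export
constraint_noise_cov <- function(C_i, C_j, Z_i, Z_j, X_i, X_j, P_Zi, P_Zj,
                                 y_gi, y_gj, p_i, p_j,
                                 sigma_a, sigma_g, sigma_gdot,
                                 gdot_lambda = c("lambda2", "lambda1")) {
  gdot_lambda <- match.arg(gdot_lambda)
  eps_cov <- function(y_g, p) {
    lm <- constraint_lambdas(y_g, p)
    ld <- if (gdot_lambda == "lambda2") lm$l2 else lm$l1
    sigma_a^2 * diag(3) + sigma_g^2 * (lm$l1 %*% t(lm$l1)) +
      sigma_gdot^2 * (ld %*% t(ld))
  }
  Si <- eps_cov(y_gi, p_i)
  Sj <- eps_cov(y_gj, p_j)
  qf <- function(u, S, v = u) as.numeric(t(u) %*% S %*% v)

  ZXi <- cross3(Z_i, X_i)          # skew(Z_i) X_i
  ZXj <- cross3(Z_j, X_j)
  XCi <- cross3(X_i, C_i)          # skew(X_i) C_i (attitude-error lever arm)
  XCj <- cross3(X_j, C_j)

  m11 <- qf(X_i, Si) + qf(X_j, Sj)
  m12 <- qf(X_i, Si, ZXi) + qf(X_j, Sj, ZXj)
  m22 <- qf(XCi, P_Zi) + qf(ZXi, Si) + qf(XCj, P_Zj) + qf(ZXj, Sj)
  make_psd(matrix(c(m11, m12, m12, m22), 2L, 2L))
}

#' Heading filter correction from the joint constraint
#'
#' Standard Kalman correction of link j's heading with the 2D constraint
#' measurement. The update is skipped (state returned unchanged, flagged)
#' when the innovation covariance is numerically singular or when either
#' link's joint-center acceleration carries no heading information (its
#' component orthogonal to the attitude axis falls below `min_excitation`) —
#' the constraint is only informative while the joint is dynamically excited.
#'
#' @param state A priori heading state of link j.
#' @param z,H Constraint measurement (see [constraint_measurement()]).
#' @param M Measurement noise covariance (see [constraint_noise_cov()]).
#' @param excitation Optional length-2 vector
#'   `(|skew(Z_i)C_i|, |skew(Z_j)C_j|)` used for the dynamic-excitation gate;
#'   `NULL` disables the gate.
#' @param min_excitation Gate threshold (m/s^2).
#' @param warn Emit a warning when the update is skipped.
#' @return Updated heading state with logical element `skipped`.
#' @export
heading_update <- function(state, z, H, M, excitation = NULL,
                           min_excitation = 0.2, warn = TRUE) {
  skip <- FALSE
  if (!is.null(excitation) && any(excitation < min_excitation)) skip <- TRUE
  S <- H %*% state$P %*% t(H) + M
  if (!skip && (!all(is.finite(S)) || rcond(S) < 1e-12)) skip <- TRUE
  if (skip) {
    if (warn) {
      warning("heading constraint update skipped: joint not dynamically excited",
              call. = FALSE)
    }
    return(list(X = state$X, P = state$P, skipped = TRUE))
  }
  K <- state$P %*% t(H) %*% solve(S)
  X <- normalize(state$X + K %*% (z - H %*% state$X))
  P <- symmetrize((diag(3) - K %*% H) %*% state$P)
  list(X = as.numeric(X), P = P, skipped = FALSE)
}
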