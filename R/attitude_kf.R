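# Attitude (inclination) Kalman filter with Gauss-Markov external-acceleration
# compensation. The state is the attitude vector Z (inertial vertical written
# in sensor coordinates); the accelerometer provides the correction through
# the model y_A = g Z + a + n_A, where the external acceleration a is tracked
# by a first-order Gauss-Markov estimate and inflates the measurement noise
# when the prediction misfits.

#' Gauss-Markov external-acceleration parameters
#'
#' `c1` is the per-sample decay of the external-acceleration estimate
#' (`a_hat^- = c1 * a_hat^+`), `c2` scales the adaptive measurement-noise
#' inflation proportional to the squared innovation norm.
#'
#' @param c1 Decay factor in `[0, 1)`.
#' @param c2 Non-negative inflation factor.
#' @return A list with elements `c1` and `c2`.
#' @export
gm_params <- function(c1 = 0.1, c2 = 0.05) {
  if (c1 < 0 || c1 >= 1 || c2 < 0) {
    imu_stop("need 0 <= c1 < 1 and c2 >= 0", "imujoint_bad_config")
  }
  list(c1 = c1, c2 = c2)
}

#' Initialize an attitude filter state
#'
#' The attitude vector starts from the (normalized) first accelerometer
#' sample -- a static-start assumption -- with an isotropic covariance.
#'
#' @param y_a First accelerometer sample (m/s^2).
#' @param sigma0_deg Initial 1-sigma attitude uncertainty (degrees).
#' @return A list with `Z` (unit attitude vector), `P` (3x3 covariance),
#'   `a_hat` (external-acceleration estimate, m/s^2).
#' @export
attitude_init <- function(y_a, sigma0_deg = 5) {
  y_a <- check_vec3(y_a)
  list(Z = normalize(y_a), P = deg2rad(sigma0_deg)^2 * diag(3), a_hat = c(0, 0, 0))
}

#' Attitude filter prediction (strapdown)
#'
#' Rotates the attitude vector by the exact per-step rotation
#' `exp(-dt * skew(y_g))` (first-order equivalent to
#' `(I - dt*skew(y_g)) Z`), propagates the covariance with the same
#' transition matrix plus gyro-driven process noise, and decays the
#' external-acceleration estimate.
#'
#' @param state Attitude state (see [attitude_init()]).
#' @param y_g Gyroscope sample (rad/s) over the step.
#' @param dt Step size (s).
#' @param sigma_g Gyroscope noise standard deviation (rad/s).
#' @param gm Gauss-Markov parameters, see [gm_params()].
#' @param q_dt_power Exponent of `dt` in the process noise
#'   `dt^q * sigma_g^2 * skew(Z) skew(Z)^T`; 2 (discrete white noise,
#'   default) or 1 (power-spectral-density convention).
#' @return Updated (a priori) attitude state.
#' @export
attitude_predict <- function(state, y_g, dt, sigma_g, gm = gm_params(),
                             q_dt_power = 2) {
  Phi <- rotvec_matrix(-dt * check_vec3(y_g))
  Z <- normalize(Phi %*% state$Z)
  Sz <- skew(Z)
  Q <- dt^q_dt_power * sigma_g^2 * (Sz %*% t(Sz))
  P <- symmetrize(Phi %*% state$P %*% t(Phi) + Q)
  list(Z = as.numeric(Z), P = P, a_hat = gm$c1 * state$a_hat)
}

#' Attitude filter correction (accelerometer update)
#'
#' Standard Kalman update with measurement model
#' `y_a - a_hat = g * Z + n_A` and adaptive noise
#' `R = sigma_a^2 I + c2^2 ||y_a - g Z^- - a_hat^-||^2 I`, so large external
#' accelerations de-weight the accelerometer. Afterward the
#' external-acceleration estimate is refreshed as `a_hat^+ = y_a - g Z^+`.
#'
#' @param state A priori attitude state.
#' @param y_a Accelerometer sample (m/s^2).
#' @param sigma_a Accelerometer noise standard deviation (m/s^2).
#' @param gm Gauss-Markov parameters, see [gm_params()].
#' @param gravity Gravitational acceleration (m/s^2).
#' @return Updated (a posteriori) attitude state.
#' @export
attitude_update <- function(state, y_a, sigma_a, gm = gm_params(),
                            gravity = 9.81) {
  y_a <- check_vec3(y_a)
  g <- gravity
  innov <- y_a - state$a_hat - g * state$Z
  Racc <- (sigma_a^2 + gm$c2^2 * sum(innov^2)) * diag(3)
  S <- g^2 * state$P + Racc
  K <- g * state$P %*% solve(S)
  Z <- normalize(state$Z + K %*% innov)
  P <- symmetrize((diag(3) - g * K) %*% state$P)
  list(Z = as.numeric(Z), P = P, a_hat = as.numeric(y_a - g * Z))
}
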