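# Rotation algebra for the DCM-based orientation filters.
#
# Frame convention used throughout the package: a link's direction cosine
# matrix R stores the inertial unit axes written in sensor coordinates as its
# rows, R = [X Y Z]^T, where X, Y, Z are the inertial x/y/z axes observed in
# the sensor frame. Consequently R maps sensor-frame coordinates to
# inertial-frame coordinates: v_inertial = R %*% v_sensor. The inertial Z axis
# points vertically upward, so Z (third row, "attitude vector") carries
# roll/pitch and X (first row, "heading vector") carries yaw.

#' Skew-symmetric (cross-product) matrix
#'
#' Returns the 3x3 matrix `S` such that `S %*% w == cross(v, w)` for any `w`.
#'
#' @param v Numeric length-3 vector.
#' @return A 3x3 skew-symmetric matrix.
#' @examples
#' skew(c(1, 0, 0)) %*% c(0, 1, 0)  # the z axis
#' @export
skew <- function(v) {
  v <- check_vec3(v)
  matrix(c(0, v[3L], -v[2L],
           -v[3L], 0, v[1L],
           v[2L], -v[1L], 0), 3L, 3L)
}

#' Rotation matrix from a rotation vector (Rodrigues formula)
#'
#' Computes `expm(skew(phi))` exactly. Used for strapdown propagation, where
#' `phi = -dt * y_G` rotates sensor-frame representations of inertial axes.
#'
#' @param phi Numeric length-3 rotation vector (radians).
#' @return A 3x3 rotation matrix.
#' @export
rotvec_matrix <- function(phi) {
  phi <- check_vec3(phi)
  th <- vnorm(phi)
  S <- skew(phi)
  if (th < 1e-12) return(diag(3) + S)
  diag(3) + (sin(th) / th) * S + ((1 - cos(th)) / th^2) * (S %*% S)
}

#' Validate a direction cosine matrix
#'
#' @param R A 3x3 matrix.
#' @param tol Orthonormality / determinant tolerance.
#' @return `TRUE` if `R` is orthonormal with determinant +1 within `tol`.
#' @export
is_dcm <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == 3L) && all(is.finite(R)) &&
    max(abs(R %*% t(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

#' Build a DCM from attitude and heading vectors
#'
#' Assembles the sensor-to-inertial rotation from the attitude vector `z`
#' (inertial vertical in sensor coordinates, trusted and normalized first) and
#' the heading vector `x` (inertial x axis in sensor coordinates, projected
#' orthogonal to `z` then normalized). The second row completes the
#' right-handed triad, `Y = Z x X`.
#'
#' @param z,x Numeric length-3 vectors; need not be unit length, must not be
#'   (anti-)parallel.
#' @param tol Degeneracy tolerance on `|z x x|` after normalization.
#' @return A 3x3 rotation matrix with rows `X`, `Y`, `Z`.
#' @export
dcm_from_attitude_heading <- function(z, x, tol = 1e-8) {
  z <- check_vec3(z); x <- check_vec3(x)
  if (vnorm(z) == 0 || vnorm(x) == 0) {
    imu_stop("attitude/heading vectors must be non-zero", "imujoint_degenerate")
  }
  zh <- normalize(z)
  xh <- normalize(x)
  if (vnorm(cross3(zh, xh)) < tol) {
    imu_stop("attitude and heading vectors are (anti-)parallel: heading undefined",
             "imujoint_degenerate")
  }
  xo <- normalize(xh - sum(xh * zh) * zh)
  yo <- cross3(zh, xo)
  rbind(X = xo, Y = yo, Z = zh)
}

#' Z-Y-X Euler angles of a rotation matrix
#'
#' Decomposes `R = Rz(alpha) %*% Ry(beta) %*% Rx(gamma)` (yaw, pitch, roll).
#' At gimbal lock (`|beta| = pi/2`) only `alpha - gamma` (or `alpha + gamma`)
#' is defined; the convention `gamma = 0` is applied and flagged.
#'
#' @param R A 3x3 rotation matrix.
#' @param lock_tol Cosine threshold below which gimbal lock is declared.
#' @return A list with `alpha`, `beta`, `gamma` (radians; `beta` in
#'   `[-pi/2, pi/2]`, others in `(-pi, pi]`) and logical `gimbal_lock`.
#' @export
euler_zyx_from_dcm <- function(R, lock_tol = 1e-7) {
  if (!is_dcm(R, tol = 1e-6)) {
    imu_stop("R is not a valid rotation matrix", "imujoint_bad_input")
  }
  s_beta <- -R[3L, 1L]
  s_beta <- min(1, max(-1, s_beta))
  beta <- asin(s_beta)
  if (sqrt(R[3L, 2L]^2 + R[3L, 3L]^2) < lock_tol) {
    # cos(beta) ~ 0: yaw and roll degenerate; fix gamma := 0
    alpha <- atan2(-R[1L, 2L], R[2L, 2L])
    return(list(alpha = alpha, beta = beta, gamma = 0, gimbal_lock = TRUE))
  }
  list(alpha = atan2(R[2L, 1L], R[1L, 1L]),
       beta = beta,
       gamma = atan2(R[3L, 2L], R[3L, 3L]),
       gimbal_lock = FALSE)
}

#' Recompose a rotation matrix from Z-Y-X Euler angles
#'
#' @param alpha,beta,gamma Yaw, pitch, roll in radians.
#' @return The 3x3 matrix `Rz(alpha) Ry(beta) Rx(gamma)`.
#' @export
dcm_from_euler_zyx <- function(alpha, beta, gamma) {
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta);  sb <- sin(beta)
  cg <- cos(gamma); sg <- sin(gamma)
  matrix(c(ca * cb, sa * cb, -sb,
           ca * sb * sg - sa * cg, sa * sb * sg + ca * cg, cb * sg,
           ca * sb * cg + sa * sg, sa * sb * cg - ca * sg, cb * cg),
         3L, 3L)
}

#' Relative rotation between two links
#'
#' For link DCMs following the package frame convention (rows = inertial axes
#' in sensor coordinates), `t(R_i) %*% R_j` maps link-j coordinates into
#' link-i coordinates; its Z-Y-X Euler angles are the joint angles.
#'
#' @param R_i,R_j 3x3 rotation matrices.
#' @return The 3x3 relative rotation `t(R_i) %*% R_j`.
#' @export
relative_dcm <- function(R_i, R_j) {
  t(R_i) %*% R_j
}
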