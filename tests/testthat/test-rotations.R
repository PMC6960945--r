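test_that("skew reproduces the cross product", {
  expect_equal(skew(c(0, 0, 0)), matrix(0, 3, 3))
  expect_equal(as.numeric(skew(c(1, 0, 0)) %*% c(0, 1, 0)), c(0, 0, 1))
  set.seed(1)
  for (rep in 1:20) {
    v <- stats::rnorm(3); w <- stats::rnorm(3)
    S <- skew(v)
    expect_equal(as.numeric(S %*% w), cross_oracle(v, w), tolerance = 1e-12)
    expect_equal(t(S), -S)
  }
})

test_that("dcm_from_attitude_heading builds orthonormal frames with trusted Z", {
  expect_equal(dcm_from_attitude_heading(c(0, 0, 1), c(1, 0, 0)),
               diag(3), ignore_attr = TRUE)

  # Gram-Schmidt oracle for a slightly off-axis heading
  R <- dcm_from_attitude_heading(c(0, 0, 1), c(1, 0.01, 0))
  expect_true(is_dcm(R, tol = 1e-9))
  expect_equal(as.numeric(R[3, ]), c(0, 0, 1), tolerance = 1e-12)
  x_gs <- c(1, 0.01, 0) / sqrt(1 + 0.01^2)  # already orthogonal to z
  expect_equal(as.numeric(R[1, ]), x_gs, tolerance = 1e-12)

  expect_error(dcm_from_attitude_heading(c(0, 0, 1), c(0, 0, 1)),
               class = "imujoint_degenerate")
  expect_error(dcm_from_attitude_heading(c(0, 0, 1), c(0, 0, -2)),
               class = "imujoint_degenerate")

  set.seed(7)
  for (rep in 1:25) {
    z <- stats::rnorm(3); x <- stats::rnorm(3)
    if (sqrt(sum(cross_oracle(z / sqrt(sum(z^2)), x / sqrt(sum(x^2)))^2)) < 1e-3) next
    R <- dcm_from_attitude_heading(z, x)
    expect_true(is_dcm(R, tol = 1e-9))
    # invariance to positive rescaling
    R2 <- dcm_from_attitude_heading(3.7 * z, 0.21 * x)
    expect_equal(R, R2, tolerance = 1e-12)
    # Z is trusted exactly, X lies in span(z, x)
    expect_equal(as.numeric(R[3, ]), z / sqrt(sum(z^2)), tolerance = 1e-12)
  }
})

test_that("euler_zyx decompose/recompose round-trips away from gimbal lock", {
  id <- euler_zyx_from_dcm(diag(3))
  expect_equal(c(id$alpha, id$beta, id$gamma), c(0, 0, 0))
  expect_false(id$gimbal_lock)

  yaw90 <- euler_zyx_from_dcm(dcm_from_euler_zyx(pi / 2, 0, 0))
  expect_equal(yaw90$alpha, pi / 2, tolerance = 1e-12)
  expect_equal(c(yaw90$beta, yaw90$gamma), c(0, 0), tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:30) {
    R <- random_rotation()
    e <- euler_zyx_from_dcm(R)
    expect_lt(max(abs(dcm_from_euler_zyx(e$alpha, e$beta, e$gamma) - R)), 1e-9)
    expect_true(abs(e$beta) <= pi / 2 + 1e-12)
  }

  # property: angle triples round-trip through the matrix
  set.seed(12)
  for (rep in 1:30) {
    a <- stats::runif(1, -pi, pi); b <- stats::runif(1, -1.4, 1.4)
    g <- stats::runif(1, -pi, pi)
    e <- euler_zyx_from_dcm(dcm_from_euler_zyx(a, b, g))
    expect_equal(c(e$alpha, e$beta, e$gamma), c(a, b, g), tolerance = 1e-9)
  }
})

test_that("gimbal lock is resolved by the gamma = 0 convention and flagged", {
  R <- dcm_from_euler_zyx(0.4, pi / 2, 0.3)
  e <- euler_zyx_from_dcm(R)
  expect_true(e$gimbal_lock)
  expect_identical(e$gamma, 0)
  # recomposition still exact: only alpha - gamma is observable at beta = pi/2
  expect_lt(max(abs(dcm_from_euler_zyx(e$alpha, e$beta, e$gamma) - R)), 1e-9)

  e2 <- euler_zyx_from_dcm(dcm_from_euler_zyx(0.4, -pi / 2, 0.3))
  expect_true(e2$gimbal_lock)
  expect_lt(max(abs(dcm_from_euler_zyx(e2$alpha, e2$beta, e2$gamma) -
                    dcm_from_euler_zyx(0.4, -pi / 2, 0.3))), 1e-9)
})

test_that("relative_dcm composes orientations correctly", {
  set.seed(21)
  R <- random_rotation()
  expect_equal(relative_dcm(R, R), diag(3), tolerance = 1e-12)
  expect_equal(relative_dcm(diag(3), R), R)
  for (rep in 1:10) {
    Ri <- random_rotation(); Rj <- random_rotation()
    Rij <- relative_dcm(Ri, Rj)
    expect_lt(max(abs(Ri %*% Rij - Rj)), 1e-12)
    expect_true(is_dcm(Rij, tol = 1e-9))
  }
})

test_that("rotvec_matrix matches the axis-angle rotation of a vector", {
  set.seed(31)
  for (rep in 1:10) {
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    th <- stats::runif(1, -2, 2)
    v <- stats::rnorm(3)
    # Rodrigues vector-rotation oracle written out directly
    v_rot <- v * cos(th) + cross_oracle(axis, v) * sin(th) +
      axis * sum(axis * v) * (1 - cos(th))
    expect_equal(as.numeric(rotvec_matrix(th * axis) %*% v), v_rot,
                 tolerance = 1e-12)
  }
  expect_equal(rotvec_matrix(c(0, 0, 0)), diag(3))
})
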