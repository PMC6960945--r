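test_that("heading prediction: identity without rotation, closed form under constant rate", {
  st <- heading_init(c(0, 0, 1), c(1, 0, 0))
  pred <- heading_predict(st, c(0, 0, 0), 0.01, 1.5e-3)
  expect_equal(pred$X, st$X)

  # constant rotation about the vertical: X precesses about sensor z
  w <- 0.9; dt <- 0.01; n <- 300
  st <- heading_init(c(0, 0, 1), c(1, 0, 0))
  for (s in seq_len(n)) st <- heading_predict(st, c(0, 0, w), dt, 0)
  th <- -w * dt * n
  expect_lt(vec_angle_deg(st$X, c(cos(th), sin(th), 0)) * pi / 180, n * dt^2)
})

test_that("process noise covariance matches Monte-Carlo E(w w^T)", {
  set.seed(123)
  X <- normalize_oracle(c(0.3, -0.8, 0.5))
  dt <- 0.01; sigma_g <- 1.5e-3
  n <- 1e5
  NG <- matrix(stats::rnorm(3 * n, sd = sigma_g), n, 3)
  # w = dt * (-skew(X)) n_G = dt * (n_G x X)
  W <- dt * cbind(NG[, 2] * X[3] - NG[, 3] * X[2],
                  NG[, 3] * X[1] - NG[, 1] * X[3],
                  NG[, 1] * X[2] - NG[, 2] * X[1])
  Q_mc <- crossprod(W) / n
  Sx <- skew(X)
  Q <- dt^2 * sigma_g^2 * (Sx %*% t(Sx))
  expect_lt(norm(Q - Q_mc, "F") / norm(Q, "F"), 0.05)
})

test_that("constraint vector C reduces correctly in special cases", {
  y_a <- c(1, 2, 3)
  expect_equal(constraint_vector(y_a, c(0, 0, 0), c(0, 0, 0), c(0.5, 0, 0)), y_a)
  expect_equal(constraint_vector(y_a, c(1, 1, 1), c(2, 2, 2), c(0, 0, 0)), y_a)
  # pure spin about z with lever arm x: centripetal -w^2 * p
  expect_equal(constraint_vector(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0), c(1, 0, 0)),
               c(-1, 0, 0), tolerance = 1e-15)
  # angular acceleration term: skew(wdot) p
  expect_equal(constraint_vector(c(0, 0, 0), c(0, 0, 0), c(0, 0, 2), c(1, 0, 0)),
               c(0, 2, 0), tolerance = 1e-15)
})

test_that("gyro differentiation is exact for linear signals and accurate for sinusoids", {
  tm <- seq(0, 2, by = 0.01)
  # constant -> zero
  s_const <- imu_series(tm, matrix(0.3, length(tm), 3), matrix(0, length(tm), 3))
  expect_equal(max(abs(differentiate_gyro(s_const))), 0)
  # linear -> exact slope at interior points
  G <- cbind(2 * tm, -1 * tm, 0.5 * tm)
  s_lin <- imu_series(tm, G, matrix(0, length(tm), 3))
  D <- differentiate_gyro(s_lin)
  expect_equal(D[2:(length(tm) - 1), 1], rep(2, length(tm) - 2), tolerance = 1e-12)
  expect_equal(D[2:(length(tm) - 1), 2], rep(-1, length(tm) - 2), tolerance = 1e-12)
  # sinusoid at 1 Hz, 100 Hz sampling: max error < 1e-2 rad/s^2 vs analytic
  G2 <- cbind(sin(2 * pi * tm), cos(2 * pi * tm), 0 * tm)
  D2 <- differentiate_gyro(imu_series(tm, G2, matrix(0, length(tm), 3)))
  Dtrue <- cbind(2 * pi * cos(2 * pi * tm), -2 * pi * sin(2 * pi * tm), 0 * tm)
  interior <- 2:(length(tm) - 1)
  expect_lt(max(abs(D2[interior, ] - Dtrue[interior, ])), 1e-2)
  expect_error(differentiate_gyro(s_const[1:2, ]), class = "imujoint_bad_input")
})

test_that("constraint measurement has zero innovation at the true state", {
  s <- short_sim(duration = 4, seed = 17, sigma_acc = 0, sigma_gyro = 0)
  tr <- s$truth; imu <- s$imu
  jt <- tr$joints[[1]]
  worst <- 0
  for (t in seq(1, length(tr$time), by = 7)) {
    l1 <- tr$links[[1]]; l2 <- tr$links[[2]]
    C1 <- constraint_vector(imu_acc(imu[[1]])[t, ], l1$omega[t, ],
                            l1$omega_dot[t, ], jt$p_a)
    C2 <- constraint_vector(imu_acc(imu[[2]])[t, ], l2$omega[t, ],
                            l2$omega_dot[t, ], jt$p_b)
    m <- constraint_measurement(C1, C2, l1$R[3, , t], l2$R[3, , t], l1$R[1, , t])
    worst <- max(worst, max(abs(m$z - m$H %*% l2$R[1, , t])))
  }
  expect_lt(worst, 1e-8)
})

test_that("static truth keeps the constraint residual at zero (gravity-only projections)", {
  cfg <- sim_config(duration = 1, seed = 2, static = TRUE,
                    sigma_acc = 0, sigma_gyro = 0)
  tr <- simulate_truth(cfg); imu <- synthesize_imu(tr)
  jt <- tr$joints[[1]]; t <- 50
  C1 <- constraint_vector(imu_acc(imu[[1]])[t, ], c(0, 0, 0), c(0, 0, 0), jt$p_a)
  C2 <- constraint_vector(imu_acc(imu[[2]])[t, ], c(0, 0, 0), c(0, 0, 0), jt$p_b)
  m <- constraint_measurement(C1, C2, tr$links[[1]]$R[3, , t],
                              tr$links[[2]]$R[3, , t], tr$links[[1]]$R[1, , t])
  expect_lt(max(abs(m$z - m$H %*% tr$links[[2]]$R[1, , t])), 1e-9)
})

test_that("measurement noise covariance matches its closed forms and Monte-Carlo", {
  # degenerate: no noise, no attitude uncertainty -> M = 0
  Z <- c(0, 0, 1); X <- c(1, 0, 0)
  M0 <- constraint_noise_cov(c(1, 1, 1), c(1, -1, 0), Z, Z, X, X,
                             matrix(0, 3, 3), matrix(0, 3, 3),
                             c(0.5, 0, 0), c(0, 0.5, 0),
                             c(0.4, 0, 0), c(0.5, 0, 0), 0, 0, 0)
  expect_lt(max(abs(M0)), 1e-12)

  # p = 0 and P_Z = 0: M11 = 2 sigma_a^2 for unit heading states
  sa <- 14.8e-3
  M1 <- constraint_noise_cov(c(1, 2, 3), c(3, 2, 1), Z, Z, X, X,
                             matrix(0, 3, 3), matrix(0, 3, 3),
                             c(1, 0, 0), c(0, 1, 0),
                             c(0, 0, 0), c(0, 0, 0), sa, 1.5e-3, 25.3e-3)
  expect_equal(M1[1, 1], 2 * sa^2, tolerance = 1e-12)

  # Monte-Carlo oracle on a generic dynamic sample
  set.seed(77)
  sim <- short_sim(duration = 2, seed = 23, sigma_acc = 0, sigma_gyro = 0)
  tr <- sim$truth; t <- 120
  l1 <- tr$links[[1]]; l2 <- tr$links[[2]]; jt <- tr$joints[[1]]
  sg <- 1.5e-3; sgd <- 25.3e-3
  P_Z1 <- (0.5 * pi / 180)^2 * diag(3)
  P_Z2 <- (0.8 * pi / 180)^2 * diag(3)
  Z1 <- l1$R[3, , t]; Z2 <- l2$R[3, , t]
  X1 <- l1$R[1, , t]; X2 <- l2$R[1, , t]
  C1 <- constraint_vector(imu_acc(sim$imu[[1]])[t, ], l1$omega[t, ],
                          l1$omega_dot[t, ], jt$p_a)
  C2 <- constraint_vector(imu_acc(sim$imu[[2]])[t, ], l2$omega[t, ],
                          l2$omega_dot[t, ], jt$p_b)
  M <- constraint_noise_cov(C1, C2, Z1, Z2, X1, X2, P_Z1, P_Z2,
                            l1$omega[t, ], l2$omega[t, ], jt$p_a, jt$p_b,
                            sa, sg, sgd)
  lam <- function(y_g, p) {
    Sp <- skew(p); Sg <- skew(y_g)
    list(l1 = Sp %*% Sg - 2 * Sg %*% Sp, l2 = -Sp)
  }
  la <- lam(l1$omega[t, ], jt$p_a); lb <- lam(l2$omega[t, ], jt$p_b)
  n <- 1e5
  draw <- function(sd) matrix(stats::rnorm(3 * n, sd = sd), n, 3)
  eps_i <- draw(sa) + draw(sg) %*% t(la$l1) + draw(sgd) %*% t(la$l2)
  eps_j <- draw(sa) + draw(sg) %*% t(lb$l1) + draw(sgd) %*% t(lb$l2)
  ze_i <- draw(0.5 * pi / 180)
  ze_j <- draw(0.8 * pi / 180)
  cr <- function(A, v) cbind(A[, 2] * v[3] - A[, 3] * v[2],
                             A[, 3] * v[1] - A[, 1] * v[3],
                             A[, 1] * v[2] - A[, 2] * v[1])
  v1 <- eps_i %*% X1 - eps_j %*% X2
  v2 <- cr(ze_i, X1) %*% C1 + eps_i %*% cross_oracle(Z1, X1) -
    cr(ze_j, X2) %*% C2 - eps_j %*% cross_oracle(Z2, X2)
  M_mc <- crossprod(cbind(v1, v2)) / n
  expect_lt(norm(M - M_mc, "F") / norm(M, "F"), 0.05)
})

test_that("heading update obeys limiting cases and reduces heading error", {
  st <- heading_init(c(0, 0, 1), c(1, 0, 0), sigma0_deg = 5)
  H <- rbind(c(5, 1, 0), c(1, -4, 0.5))
  M <- diag(c(1e-3, 1e-3))
  # zero innovation: state unchanged
  z0 <- as.numeric(H %*% st$X)
  upd <- heading_update(st, z0, H, M)
  expect_equal(upd$X, st$X, tolerance = 1e-12)
  expect_false(upd$skipped)
  # uninformative measurement (M huge): state unchanged within 1e-6
  upd2 <- heading_update(st, z0 + c(2, -1), H, 1e12 * diag(2))
  expect_lt(max(abs(upd2$X - st$X)), 1e-6)
  # covariance stays symmetric PSD
  expect_equal(upd$P, t(upd$P))
  expect_gte(min(eigen(upd$P, symmetric = TRUE)$values), -1e-12)

  # an erroneous heading is pulled toward the constraint-consistent direction
  s <- short_sim(duration = 4, seed = 29, sigma_acc = 0, sigma_gyro = 0)
  tr <- s$truth; jt <- tr$joints[[1]]; t <- 250
  l1 <- tr$links[[1]]; l2 <- tr$links[[2]]
  C1 <- constraint_vector(imu_acc(s$imu[[1]])[t, ], l1$omega[t, ],
                          l1$omega_dot[t, ], jt$p_a)
  C2 <- constraint_vector(imu_acc(s$imu[[2]])[t, ], l2$omega[t, ],
                          l2$omega_dot[t, ], jt$p_b)
  m <- constraint_measurement(C1, C2, l1$R[3, , t], l2$R[3, , t], l1$R[1, , t])
  X_true <- l2$R[1, , t]
  # 5-degree yaw offset about the attitude axis
  X_bad <- as.numeric(rotvec_matrix(deg2rad_oracle(5) * l2$R[3, , t]) %*% X_true)
  st_bad <- list(X = X_bad, P = (5 * pi / 180)^2 * diag(3))
  Mc <- constraint_noise_cov(C1, C2, l1$R[3, , t], l2$R[3, , t],
                             l1$R[1, , t], X_bad, matrix(0, 3, 3), matrix(0, 3, 3),
                             l1$omega[t, ], l2$omega[t, ], jt$p_a, jt$p_b,
                             14.8e-3, 1.5e-3, 25.3e-3)
  upd3 <- heading_update(st_bad, m$z, m$H, Mc)
  expect_false(upd3$skipped)
  expect_lt(vec_angle_deg(upd3$X, X_true), vec_angle_deg(X_bad, X_true))
})

test_that("the update is skipped with a warning when the joint is not excited", {
  st <- heading_init(c(0, 0, 1), c(1, 0, 0))
  H <- rbind(c(0.01, 0, 0), c(0, 0.01, 0))
  M <- 1e-4 * diag(2)
  expect_warning(
    upd <- heading_update(st, c(0, 0), H, M, excitation = c(0.05, 1)),
    "skipped")
  expect_true(upd$skipped)
  expect_equal(upd$X, st$X)
  # singular innovation covariance is also caught
  upd2 <- heading_update(st, c(0, 0), matrix(0, 2, 3), matrix(0, 2, 2),
                         warn = FALSE)
  expect_true(upd2$skipped)
})
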