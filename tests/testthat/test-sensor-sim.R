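test_that("static configuration yields constant orientation and zero motion", {
  cfg <- sim_config(duration = 2, seed = 1, static = TRUE,
                    sigma_acc = 0, sigma_gyro = 0)
  tr <- simulate_truth(cfg)
  N <- length(tr$time)
  for (k in 1:2) {
    expect_lt(max(abs(tr$links[[k]]$R[, , N] - tr$links[[k]]$R[, , 1])), 1e-12)
    expect_equal(max(abs(tr$links[[k]]$omega)), 0)
    expect_lt(max(abs(tr$links[[k]]$acc)), 1e-12)
  }
  # rest reading: gravity along the attitude vector, zero rates
  imu <- synthesize_imu(tr)
  Z1 <- tr$links[[1]]$R[3, , 1]
  expect_equal(as.numeric(unlist(imu[[1]][1, c("ax", "ay", "az")])),
               9.81 * Z1, tolerance = 1e-12)
  expect_equal(max(abs(imu_gyro(imu[[1]]))), 0)
})

test_that("truth satisfies the shared-joint-center acceleration constraint", {
  for (seed in c(2, 9)) {
    tr <- simulate_truth(sim_config(duration = 5, seed = seed,
                                    sigma_acc = 0, sigma_gyro = 0))
    expect_lt(constraint_residual(tr), 1e-6)
    # per-sample orientations stay valid rotations
    idx <- c(1, 250, 500)
    for (t in idx) {
      expect_true(is_dcm(tr$links[[1]]$R[, , t], tol = 1e-9))
      expect_true(is_dcm(tr$links[[2]]$R[, , t], tol = 1e-9))
    }
    # stored joint angles equal Euler of the relative DCM
    t <- 300
    Rel <- relative_dcm(tr$links[[1]]$R[, , t], tr$links[[2]]$R[, , t])
    e <- euler_zyx_from_dcm(Rel)
    expect_equal(as.numeric(tr$joints[[1]]$euler[t, ]),
                 c(e$alpha, e$beta, e$gamma), tolerance = 1e-9)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  a <- short_sim(duration = 2, seed = 5)
  b <- short_sim(duration = 2, seed = 5)
  expect_identical(a$truth$links[[1]]$R, b$truth$links[[1]]$R)
  expect_identical(a$imu[[1]], b$imu[[1]])
  c2 <- short_sim(duration = 2, seed = 6)
  expect_false(identical(a$imu[[1]], c2$imu[[1]]))
})

test_that("noise injection matches the configured levels and sensor model", {
  # noiseless signals equal the model exactly
  tr <- simulate_truth(sim_config(duration = 3, seed = 3,
                                  sigma_acc = 0, sigma_gyro = 0))
  imu <- synthesize_imu(tr)
  expect_equal(imu_gyro(imu[[1]]), tr$links[[1]]$omega, tolerance = 1e-15)
  Zs <- t(tr$links[[1]]$R[3, , ])
  expect_equal(imu_acc(imu[[1]]), 9.81 * Zs + tr$links[[1]]$acc,
               tolerance = 1e-12)

  # Monte-Carlo: sample std of the injected gyro noise within 5% of sigma
  cfg <- sim_config(duration = 60, sample_rate = 100, seed = 8)
  tr2 <- simulate_truth(cfg)
  imu2 <- synthesize_imu(tr2)
  resid <- imu_gyro(imu2[[1]]) - tr2$links[[1]]$omega
  expect_lt(abs(stats::sd(resid) / 1.5e-3 - 1), 0.05)
  resid_a <- imu_acc(imu2[[1]]) - 9.81 * t(tr2$links[[1]]$R[3, , ]) -
    tr2$links[[1]]$acc
  expect_lt(abs(stats::sd(resid_a) / 14.8e-3 - 1), 0.05)
  # noise is zero-mean: empirical mean error small relative to sigma
  expect_lt(abs(mean(resid)), 3 * 1.5e-3 / sqrt(length(resid)))
})

test_that("three-link chains satisfy the constraint at every joint", {
  cfg <- sim_config(duration = 4, seed = 13, n_links = 3,
                    sigma_acc = 0, sigma_gyro = 0)
  tr <- simulate_chain(3, cfg)
  expect_length(tr$joints, 2)
  expect_true(all(constraint_residual(tr) < 1e-6))
  imu <- synthesize_imu(tr)
  expect_length(imu, 3)
})

test_that("degenerate chain and config requests error", {
  expect_error(simulate_chain(1), class = "imujoint_bad_config")
  expect_error(sim_config(duration = -1), class = "imujoint_bad_config")
  expect_error(sim_config(sigma_acc = -0.1), class = "imujoint_bad_config")
})

test_that("two-link chain is the two-link simulator", {
  cfg <- sim_config(duration = 2, seed = 4)
  expect_identical(simulate_chain(2, cfg)$links[[2]]$R,
                   simulate_truth(cfg)$links[[2]]$R)
})

test_that("gyro bias injection shifts the gyroscope columns only", {
  s <- short_sim(duration = 1, seed = 2)
  b <- add_gyro_bias(s$imu[[1]], c(0.01, -0.02, 0.03))
  expect_equal(b$gx, s$imu[[1]]$gx + 0.01)
  expect_equal(b$gz, s$imu[[1]]$gz + 0.03)
  expect_identical(b$ax, s$imu[[1]]$ax)
})
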