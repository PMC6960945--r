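library(imujoint)
# local-cubic (Savitzky-Golay) first-derivative weights at window center
sg_deriv_weights <- function(half, dt) {
  x <- (-half):half
  X <- cbind(1, x, x^2, x^3)
  W <- solve(crossprod(X), t(X))    # 4 x (2h+1)
  W[2, ] / dt
}
sg_derivative <- function(G, dt, half = 10) {
  w <- sg_deriv_weights(half, dt)
  N <- nrow(G)
  D <- matrix(NA_real_, N, 3)
  for (a in 1:3) D[, a] <- stats::filter(G[, a], rev(w), sides = 2)
  # one-sided fallback near edges: reuse nearest valid interior value
  for (t in 1:half) D[t, ] <- D[half + 1, ]
  for (t in (N - half + 1):N) D[t, ] <- D[N - half, ]
  D
}
# accuracy on noiseless truth
cfg <- sim_config(duration = 20, seed = 3, sigma_acc = 0, sigma_gyro = 0)
tr <- simulate_truth(cfg); imu <- synthesize_imu(tr)
G <- cbind(imu[[1]]$gx, imu[[1]]$gy, imu[[1]]$gz)
for (h in c(5, 10, 15)) {
  D <- sg_derivative(G, 0.01, h)
  int <- (h+1):(nrow(G)-h)
  cat("half", h, "max |err| noiseless:", max(abs(D[int,] - tr$links[[1]]$omega_dot[int,])), "\n")
}
# noise gain
set.seed(1); n <- matrix(rnorm(3*20000, sd=1.5e-3), ncol=3)
cat("central diff noise sd:", sd((n[3:20000,1]-n[1:19998,1])/(0.02)), "\n")
for (h in c(5,10,15)) cat("SG half", h, "noise sd:", sd(sg_derivative(n, 0.01, h)[,1]), "\n")
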