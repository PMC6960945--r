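library(imujoint)
p_true <- c(0.498, -0.001, -0.031, 0.512, 0.001, -0.027)
errs <- matrix(NA, 10, 6)
for (k in 1:10) {
  cfg <- sim_config(duration = 180, seed = 600 + k)
  tr <- simulate_truth(cfg); imu <- synthesize_imu(tr)
  cal <- estimate_joint_vectors(imu[[1]], imu[[2]])
  errs[k, ] <- c(cal$p_i, cal$p_j) - p_true
}
cat("signed mean (mm):", round(1000*colMeans(errs), 2), "\n")
cat("sd (mm):", round(1000*apply(errs, 2, sd), 2), "\n")
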