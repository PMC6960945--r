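library(imujoint)
cfg <- sim_config(duration = 60, seed = 11, sigma_acc = 0, sigma_gyro = 0)
tr <- simulate_truth(cfg)
imu <- synthesize_imu(tr)
pcfg <- pipeline_config_from_truth(tr, exact_init = TRUE)

# rerun pipeline but capture per-link states: reimplement loop via exported ops
G <- list(cbind(imu[[1]]$gx,imu[[1]]$gy,imu[[1]]$gz), cbind(imu[[2]]$gx,imu[[2]]$gy,imu[[2]]$gz))
A <- list(cbind(imu[[1]]$ax,imu[[1]]$ay,imu[[1]]$az), cbind(imu[[2]]$ax,imu[[2]]$ay,imu[[2]]$az))
Gd <- list(differentiate_gyro(imu[[1]]), differentiate_gyro(imu[[2]]))
N <- nrow(imu[[1]]); dt <- imu[[1]]$t[2]-imu[[1]]$t[1]
att <- list(); hd <- list()
for (k in 1:2) {
  att[[k]] <- attitude_init(A[[k]][1,], 1e-3)
  att[[k]]$Z <- tr$links[[k]]$R[3,,1]
  hd[[k]] <- heading_init(att[[k]]$Z, tr$links[[k]]$R[1,,1], 1e-3)
}
zerr <- matrix(0,N,2); xerr <- matrix(0,N,2)
ang <- function(u,v) acos(min(1,max(-1,sum(u*v)/sqrt(sum(u*u)*sum(v*v)))))*180/pi
pj <- pcfg$p_joints[[1]]
for (t in 1:N) {
  if (t>1) for (k in 1:2) {
    u <- (G[[k]][t-1,]+G[[k]][t,])/2 + (dt/12)*c(
      G[[k]][t-1,2]*G[[k]][t,3]-G[[k]][t-1,3]*G[[k]][t,2],
      G[[k]][t-1,3]*G[[k]][t,1]-G[[k]][t-1,1]*G[[k]][t,3],
      G[[k]][t-1,1]*G[[k]][t,2]-G[[k]][t-1,2]*G[[k]][t,1])
    att[[k]] <- attitude_predict(att[[k]], u, dt, pcfg$sigma_gyro, pcfg$gm)
    hd[[k]] <- heading_predict(hd[[k]], u, dt, pcfg$sigma_gyro)
  }
  for (k in 1:2) att[[k]] <- attitude_update(att[[k]], A[[k]][t,], pcfg$sigma_acc, pcfg$gm, pcfg$gravity)
  C1 <- constraint_vector(A[[1]][t,],G[[1]][t,],Gd[[1]][t,],pj$p_a)
  C2 <- constraint_vector(A[[2]][t,],G[[2]][t,],Gd[[2]][t,],pj$p_b)
  m <- constraint_measurement(C1,C2,att[[1]]$Z,att[[2]]$Z,hd[[1]]$X)
  M <- constraint_noise_cov(C1,C2,att[[1]]$Z,att[[2]]$Z,hd[[1]]$X,hd[[2]]$X,
                            att[[1]]$P,att[[2]]$P,G[[1]][t,],G[[2]][t,],pj$p_a,pj$p_b,
                            pcfg$sigma_acc,pcfg$sigma_gyro,pcfg$sigma_gdot)
  exc <- c(sqrt(sum((c(att[[1]]$Z[2]*C1[3]-att[[1]]$Z[3]*C1[2], att[[1]]$Z[3]*C1[1]-att[[1]]$Z[1]*C1[3], att[[1]]$Z[1]*C1[2]-att[[1]]$Z[2]*C1[1]))^2)), 1)
  upd <- heading_update(hd[[2]], m$z, m$H, M, excitation=exc, warn=FALSE)
  hd[[2]] <- list(X=upd$X, P=upd$P)
  for (k in 1:2) { zerr[t,k] <- ang(att[[k]]$Z, tr$links[[k]]$R[3,,t]); xerr[t,k] <- ang(hd[[k]]$X, tr$links[[k]]$R[1,,t]) }
}
cat("max Z err (deg): ", apply(zerr,2,max), "\n")
cat("max X err (deg): ", apply(xerr,2,max), "\n")
i <- which.max(xerr[,2]); cat("worst X2 at t:", imu[[1]]$t[i], "\n")
cat("X err around t=32.4:", xerr[3242,], " Z err:", zerr[3242,], "\n")
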