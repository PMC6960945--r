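# Joint-angle evaluation metrics.

# shortest-arc angular difference in radians, in (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' RMSE of estimated joint Euler angles against a truth reference
#'
#' Per-angle root mean squared error on shortest-arc (wrapped) differences,
#' reported in degrees, plus the arithmetic mean of the three and per-link
#' yaw RMSEs (diagnostics for the drift pattern: per-link yaw may drift while
#' the joint angle stays driftless).
#'
#' @param est,truth `joint_angles` data frames on the same time base (e.g.
#'   from [estimate_joint_angles()] and [truth_joint_angles()]).
#' @return A list of class `rmse_report`: `roll`, `pitch`, `yaw`, `average`,
#'   `yaw_link_i`, `yaw_link_j` (degrees).
#' @export
rmse_euler <- function(est, truth) {
  if (nrow(est) != nrow(truth) || max(abs(est$t - truth$t)) > 1e-6) {
    imu_stop("estimate and truth series are not aligned", "imujoint_bad_input")
  }
  rmse_deg <- function(a, b) rad2deg(sqrt(mean(wrap_angle(a - b)^2)))
  roll <- rmse_deg(est$gamma, truth$gamma)
  pitch <- rmse_deg(est$beta, truth$beta)
  yaw <- rmse_deg(est$alpha, truth$alpha)
  structure(list(roll = roll, pitch = pitch, yaw = yaw,
                 average = mean(c(roll, pitch, yaw)),
                 yaw_link_i = rmse_deg(est$yaw_i, truth$yaw_i),
                 yaw_link_j = rmse_deg(est$yaw_j, truth$yaw_j)),
            class = "rmse_report")
}

#' Per-sample absolute joint-angle errors
#'
#' @param est,truth Aligned `joint_angles` data frames.
#' @return A data frame with `t` and absolute wrapped errors (degrees) for
#'   `alpha`, `beta`, `gamma` and per-link yaws.
#' @export
angle_errors <- function(est, truth) {
  if (nrow(est) != nrow(truth) || max(abs(est$t - truth$t)) > 1e-6) {
    imu_stop("estimate and truth series are not aligned", "imujoint_bad_input")
  }
  data.frame(t = est$t,
             alpha = abs(rad2deg(wrap_angle(est$alpha - truth$alpha))),
             beta = abs(rad2deg(wrap_angle(est$beta - truth$beta))),
             gamma = abs(rad2deg(wrap_angle(est$gamma - truth$gamma))),
             yaw_i = abs(rad2deg(wrap_angle(est$yaw_i - truth$yaw_i))),
             yaw_j = abs(rad2deg(wrap_angle(est$yaw_j - truth$yaw_j))))
}

#' @export
print.rmse_report <- function(x, ...) {
  cat("Joint angle RMSE (deg)\n")
  cat(sprintf("  roll %6.3f  pitch %6.3f  yaw %6.3f  | average %6.3f\n",
              x$roll, x$pitch, x$yaw, x$average))
  cat(sprintf("  per-link yaw: i %7.3f  j %7.3f\n", x$yaw_link_i, x$yaw_link_j))
  invisible(x)
}
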