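# End-to-end joint-angle estimation: per time step, attitude KF (both links)
# -> heading prediction (both links) -> constraint correction of the distal
# link -> DCM assembly -> Z-Y-X Euler joint angles. Generalizes to an n-link
# chain by propagating the correction sequentially from the base link.

#' Pipeline configuration
#'
#' @param p_i,p_j Sensor-to-joint-center vectors (m) of the proximal (i) and
#'   distal (j) link for the two-link case; defaults are the measured vectors
#'   of the rigid two-link rig.
#' @param p_joints For chains: list with one element per joint, each a list
#'   `list(p_a =, p_b =)` giving the coupled links' sensor-to-joint vectors.
#'   Overrides `p_i`/`p_j`.
#' @param sigma_acc,sigma_gyro Accelerometer (m/s^2) and gyroscope (rad/s)
#'   noise standard deviations used by the filters.
#' @param sigma_gdot Noise standard deviation of the differentiated gyroscope
#'   signal (rad/s^2), used in the constraint noise covariance.
#' @param gm Gauss-Markov external-acceleration parameters ([gm_params()]).
#' @param method `"proposed"` (constraint correction), `"prediction_only"`
#'   (no heading correction anywhere; shows drift), or `"oracle_attitude"`
#'   (externally supplied true attitude vectors, headings still estimated).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param q_dt_power `dt` exponent of the heading-filter gyro process noise
#'   (1 = the power-spectral-density convention, default; 2 = discrete white
#'   noise). The lower exponent gives the heading correction a shorter time
#'   constant, which also absorbs slow unmodeled gyro errors (bias).
#' @param att_q_dt_power `dt` exponent of the attitude-filter process noise
#'   (2, discrete, default: a low attitude gain limits external-acceleration
#'   leakage).
#' @param gdot_lambda Lambda matrix for the differentiated-gyro noise term in
#'   the constraint covariance (`"lambda2"` default; see
#'   [constraint_noise_cov()]).
#' @param min_excitation Dynamic-excitation gate (m/s^2) below which the
#'   constraint update is skipped.
#' @param init Optional list of per-link initial states, each
#'   `list(Z =, X =)` (sensor-frame unit vectors). Defaults: attitude from
#'   the first accelerometer sample, heading from the sensor x axis.
#' @param att_sigma0_deg,head_sigma0_deg Initial attitude / heading 1-sigma
#'   uncertainties (degrees).
#' @param oracle_zero_att_cov For `method = "oracle_attitude"`: treat the
#'   supplied attitudes as exact (zero attitude covariance in the constraint
#'   noise model).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(p_i = DEFAULT_P$p_i, p_j = DEFAULT_P$p_j,
                            p_joints = NULL,
                            sigma_acc = 14.8e-3, sigma_gyro = 1.5e-3,
                            sigma_gdot = 25.3e-3, gm = gm_params(),
                            method = c("proposed", "prediction_only", "oracle_attitude"),
                            gravity = 9.81, q_dt_power = 1, att_q_dt_power = 2,
                            gdot_lambda = "lambda2", min_excitation = 0.2,
                            init = NULL, att_sigma0_deg = 5,
                            head_sigma0_deg = 10,
                            oracle_zero_att_cov = TRUE) {
  method <- match.arg(method)
  if (is.null(p_joints)) {
    p_joints <- list(list(p_a = check_vec3(p_i), p_b = check_vec3(p_j)))
  }
  structure(list(p_joints = p_joints, sigma_acc = sigma_acc,
                 sigma_gyro = sigma_gyro, sigma_gdot = sigma_gdot, gm = gm,
                 method = method, gravity = gravity, q_dt_power = q_dt_power,
                 att_q_dt_power = att_q_dt_power,
                 gdot_lambda = gdot_lambda, min_excitation = min_excitation,
                 init = init, att_sigma0_deg = att_sigma0_deg,
                 head_sigma0_deg = head_sigma0_deg,
                 oracle_zero_att_cov = oracle_zero_att_cov),
            class = "pipeline_config")
}

#' Pipeline configuration from a simulated truth
#'
#' Copies geometry and noise levels from a simulation config and (optionally)
#' the exact initial states from the truth.
#'
#' @param truth A `chain_truth`.
#' @param exact_init Use the true initial attitude/heading vectors, with
#'   correspondingly tiny initial covariances (an exactly known start has
#'   essentially no uncertainty).
#' @param ... Further arguments passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_truth <- function(truth, exact_init = TRUE, ...) {
  sc <- truth$config
  pj <- lapply(truth$joints, function(jt) list(p_a = jt$p_a, p_b = jt$p_b))
  extra <- list(...)
  args <- list(p_joints = pj, sigma_acc = sc$sigma_acc,
               sigma_gyro = sc$sigma_gyro, gravity = sc$gravity)
  if (exact_init) {
    args$init <- lapply(truth$links, function(lk) {
      list(Z = lk$R[3L, , 1L], X = lk$R[1L, , 1L])
    })
    if (is.null(extra$att_sigma0_deg)) args$att_sigma0_deg <- 1e-5
    if (is.null(extra$head_sigma0_deg)) args$head_sigma0_deg <- 1e-5
  }
  do.call(pipeline_config, c(args[setdiff(names(args), names(extra))], extra))
}

#' True attitude-vector sequences of a simulated truth
#'
#' For `method = "oracle_attitude"`: the attitude vectors an external optical
#' reference would supply.
#'
#' @param truth A `chain_truth`.
#' @return List (per link) of Nx3 matrices of unit attitude vectors.
#' @export
attitude_truth_from <- function(truth) {
  lapply(truth$links, function(lk) t(lk$R[3L, , ]))
}

#' Estimate joint angles of a two-link system
#'
#' Runs the full sequential filter on two synchronized IMU series and returns
#' the joint Euler-angle time series together with per-link yaw diagnostics.
#'
#' @param imu_i,imu_j `imu_series` of the proximal and distal link
#'   (synchronized, equal length, uniform rate).
#' @param cfg A [pipeline_config()].
#' @param attitude_truth For `method = "oracle_attitude"`: list of two Nx3
#'   matrices of true attitude vectors (see [attitude_truth_from()]).
#' @return A data frame of class `joint_angles` with columns `t`, `alpha`,
#'   `beta`, `gamma` (joint yaw/pitch/roll, rad), `yaw_i`, `yaw_j` (per-link
#'   yaw diagnostics, rad), `skipped` (constraint update skipped), `gimbal`
#'   (gimbal-lock convention applied).
#' @export
estimate_joint_angles <- function(imu_i, imu_j, cfg = pipeline_config(),
                                  attitude_truth = NULL) {
  estimate_chain_angles(list(imu_i, imu_j), cfg, attitude_truth)[[1L]]
}

#' Estimate all joint angles of an n-link chain
#'
#' The base link's heading is obtained by prediction only; each subsequent
#' link's heading is corrected against its (already determined) predecessor
#' using the shared-joint acceleration constraint, propagating sequentially
#' along the chain.
#'
#' @param imu_list List of `imu_series`, one per link, synchronized.
#' @param cfg A [pipeline_config()] with `length(imu_list) - 1` joint
#'   geometries.
#' @param attitude_truth Optional list of per-link true attitude matrices
#'   (for `method = "oracle_attitude"`).
#' @return A list of `joint_angles` data frames, one per joint.
#' @export
estimate_chain_angles <- function(imu_list, cfg = pipeline_config(),
                                  attitude_truth = NULL) {
  L <- length(imu_list)
  if (L < 2L) imu_stop("need at least two links", "imujoint_bad_input")
  if (length(cfg$p_joints) != L - 1L) {
    imu_stop("cfg$p_joints must have one entry per joint (n_links - 1)",
             "imujoint_bad_input")
  }
  N <- nrow(imu_list[[1L]])
  for (s in imu_list) {
    if (nrow(s) != N || max(abs(s$t - imu_list[[1L]]$t)) > 1e-9) {
      imu_stop("IMU series must be synchronized with equal length",
               "imujoint_bad_input")
    }
  }
  if (N < 3L) imu_stop("series too short", "imujoint_bad_input")
  dt <- imu_dt(imu_list[[1L]])
  oracle <- cfg$method == "oracle_attitude"
  if (oracle) {
    if (is.null(attitude_truth) || length(attitude_truth) != L) {
      imu_stop("method 'oracle_attitude' needs one attitude matrix per link",
               "imujoint_bad_input")
    }
  }

  G <- lapply(imu_list, imu_gyro)
  A <- lapply(imu_list, imu_acc)
  Gd <- lapply(imu_list, differentiate_gyro)

  att <- vector("list", L); hd <- vector("list", L)
  for (k in seq_len(L)) {
    ini <- if (is.null(cfg$init)) NULL else cfg$init[[k]]
    att[[k]] <- attitude_init(A[[k]][1L, ], cfg$att_sigma0_deg)
    if (!is.null(ini$Z)) att[[k]]$Z <- normalize(ini$Z)
    hd[[k]] <- heading_init(att[[k]]$Z, ini$X, cfg$head_sigma0_deg)
  }

  nj <- L - 1L
  out_ang <- lapply(seq_len(nj), function(k)
    matrix(NA_real_, N, 3L, dimnames = list(NULL, c("alpha", "beta", "gamma"))))
  out_skip <- matrix(FALSE, N, nj)
  out_gimbal <- matrix(FALSE, N, nj)
  yaw <- matrix(NA_real_, N, L)

  zero3 <- matrix(0, 3L, 3L)
  Rlink <- vector("list", L)

  for (t in seq_len(N)) {
    if (t > 1L) {
      for (k in seq_len(L)) {
        # trapezoidal effective rate with two-sample coning correction
        u <- (G[[k]][t - 1L, ] + G[[k]][t, ]) / 2 +
          (dt / 12) * cross3(G[[k]][t - 1L, ], G[[k]][t, ])
        if (!oracle) {
          att[[k]] <- attitude_predict(att[[k]], u, dt, cfg$sigma_gyro,
                                       cfg$gm, cfg$att_q_dt_power)
        }
        hd[[k]] <- heading_predict(hd[[k]], u, dt, cfg$sigma_gyro,
                                     cfg$q_dt_power)
      }
    }
    for (k in seq_len(L)) {
      if (oracle) {
        att[[k]]$Z <- attitude_truth[[k]][t, ]
        if (cfg$oracle_zero_att_cov) att[[k]]$P <- zero3
      } else {
        att[[k]] <- attitude_update(att[[k]], A[[k]][t, ], cfg$sigma_acc,
                                    cfg$gm, cfg$gravity)
      }
    }
    if (cfg$method != "prediction_only") {
      for (k in seq_len(nj)) {
        a <- k; b <- k + 1L
        pj <- cfg$p_joints[[k]]
        C_a <- constraint_vector(A[[a]][t, ], G[[a]][t, ], Gd[[a]][t, ], pj$p_a)
        C_b <- constraint_vector(A[[b]][t, ], G[[b]][t, ], Gd[[b]][t, ], pj$p_b)
        meas <- constraint_measurement(C_a, C_b, att[[a]]$Z, att[[b]]$Z,
                                       hd[[a]]$X)
        M <- constraint_noise_cov(C_a, C_b, att[[a]]$Z, att[[b]]$Z,
                                  hd[[a]]$X, hd[[b]]$X,
                                  att[[a]]$P, att[[b]]$P,
                                  G[[a]][t, ], G[[b]][t, ], pj$p_a, pj$p_b,
                                  cfg$sigma_acc, cfg$sigma_gyro, cfg$sigma_gdot,
                                  cfg$gdot_lambda)
        exc <- c(vnorm(cross3(att[[a]]$Z, C_a)), vnorm(cross3(att[[b]]$Z, C_b)))
        upd <- heading_update(hd[[b]], meas$z, meas$H, M, excitation = exc,
                              min_excitation = cfg$min_excitation, warn = FALSE)
        out_skip[t, k] <- upd$skipped
        hd[[b]] <- list(X = upd$X, P = upd$P)
      }
    }
    for (k in seq_len(L)) {
      Rlink[[k]] <- dcm_from_attitude_heading(att[[k]]$Z, hd[[k]]$X)
      yaw[t, k] <- atan2(Rlink[[k]][2L, 1L], Rlink[[k]][1L, 1L])
    }
    for (k in seq_len(nj)) {
      Rel <- crossprod(Rlink[[k]], Rlink[[k + 1L]])
      out_gimbal[t, k] <- sqrt(Rel[3L, 2L]^2 + Rel[3L, 3L]^2) < 1e-7
      out_ang[[k]][t, ] <- euler_zyx_fast(Rel)
    }
  }

  n_skip <- sum(out_skip)
  if (n_skip > 0L) {
    warning(sprintf("%d of %d heading constraint updates skipped (insufficient joint excitation)",
                    n_skip, N * nj), call. = FALSE)
  }

  lapply(seq_len(nj), function(k) {
    structure(data.frame(t = imu_list[[1L]]$t,
                         alpha = out_ang[[k]][, "alpha"],
                         beta = out_ang[[k]][, "beta"],
                         gamma = out_ang[[k]][, "gamma"],
                         yaw_i = yaw[, k], yaw_j = yaw[, k + 1L],
                         skipped = out_skip[, k], gimbal = out_gimbal[, k]),
              class = c("joint_angles", "data.frame"),
              method = cfg$method)
  })
}

#' True joint-angle series of a simulated truth
#'
#' Packs the truth reference into the same `joint_angles` layout used by the
#' estimator, for direct comparison with [rmse_euler()].
#'
#' @param truth A `chain_truth`.
#' @param joint Joint index.
#' @return A `joint_angles` data frame (true angles; `skipped`/`gimbal`
#'   all `FALSE`).
#' @export
truth_joint_angles <- function(truth, joint = 1L) {
  jt <- truth$joints[[joint]]
  Ra <- truth$links[[jt$link_a]]$R
  Rb <- truth$links[[jt$link_b]]$R
  structure(data.frame(t = truth$time,
                       alpha = jt$euler[, "alpha"],
                       beta = jt$euler[, "beta"],
                       gamma = jt$euler[, "gamma"],
                       yaw_i = atan2(Ra[2L, 1L, ], Ra[1L, 1L, ]),
                       yaw_j = atan2(Rb[2L, 1L, ], Rb[1L, 1L, ]),
                       skipped = FALSE, gimbal = FALSE),
            class = c("joint_angles", "data.frame"),
            method = "truth")
}
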