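# CSV/JSON/YAML interchange. On-disk units are SI (s, rad/s, m/s^2); joint
# angles are written in degrees for human inspection.

fmt_num <- function(x) sprintf("%.17g", x)

write_num_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = names(df))
}

read_num_csv <- function(path, expected_cols) {
  if (!file.exists(path)) {
    imu_stop(sprintf("file not found: %s", path), "imujoint_bad_file")
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) imu_stop(sprintf("malformed file %s: %s", path,
                                         conditionMessage(e)),
                                 "imujoint_bad_file"))
  miss <- setdiff(expected_cols, names(df))
  if (length(miss) > 0L) {
    imu_stop(sprintf("malformed file %s: missing columns %s", path,
                     paste(miss, collapse = ", ")), "imujoint_bad_file")
  }
  if (nrow(df) == 0L) {
    imu_stop(sprintf("malformed file %s: no data rows (line 2 onward empty)", path),
             "imujoint_bad_file")
  }
  for (cl in expected_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      imu_stop(sprintf("malformed file %s: non-numeric value in column '%s' at line %d",
                       path, cl, bad[1L] + 1L), "imujoint_bad_file")
    }
    df[[cl]] <- v
  }
  df
}

#' Write an IMU series to CSV
#'
#' Canonical interchange format: columns `t,gx,gy,gz,ax,ay,az` (s, rad/s,
#' m/s^2), header row, full double precision (lossless round trip).
#'
#' @param series An `imu_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(series, path) {
  write_num_csv(series[, c("t", "gx", "gy", "gz", "ax", "ay", "az")], path)
  invisible(path)
}

#' Read an IMU series from CSV
#'
#' Validates uniform sampling (1e-6 s tolerance) and warns when the median
#' accelerometer norm is outside 5-15 m/s^2 (likely wrong units: the gravity
#' magnitude should dominate).
#'
#' @param path CSV file written by [write_imu_csv()].
#' @return An `imu_series`.
#' @export
read_imu_csv <- function(path) {
  df <- read_num_csv(path, c("t", "gx", "gy", "gz", "ax", "ay", "az"))
  if (nrow(df) >= 3L) {
    dts <- diff(df$t)
    if (max(abs(dts - dts[1L])) > 1e-6) {
      imu_stop(sprintf("non-uniform sampling in %s (max deviation %.3g s)",
                       path, max(abs(dts - dts[1L]))), "imujoint_bad_file")
    }
  }
  med_a <- stats::median(sqrt(df$ax^2 + df$ay^2 + df$az^2))
  if (med_a < 5 || med_a > 15) {
    warning(sprintf("median |y_A| = %.2f m/s^2 outside [5, 15]: check units", med_a),
            call. = FALSE)
  }
  imu_series(df$t, cbind(df$gx, df$gy, df$gz), cbind(df$ax, df$ay, df$az))
}

#' Write a simulated truth reference to CSV
#'
#' One row per sample: time plus each link's DCM flattened row-major
#' (`R<k>_11 ... R<k>_33`).
#'
#' @param truth A `chain_truth`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  N <- length(truth$time)
  cols <- list(t = truth$time)
  for (k in seq_len(truth$n_links)) {
    for (r in 1:3) for (cc in 1:3) {
      cols[[sprintf("R%d_%d%d", k, r, cc)]] <- truth$links[[k]]$R[r, cc, ]
    }
  }
  write_num_csv(as.data.frame(cols), path)
  invisible(path)
}

#' Read a truth-reference CSV
#'
#' @param path CSV written by [write_truth_csv()].
#' @return A list with `time` and `R` (list of 3x3xN arrays, one per link).
#' @export
read_truth_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"t" %in% names(df)) {
    imu_stop(sprintf("malformed truth file %s: no 't' column", path),
             "imujoint_bad_file")
  }
  n_links <- 0L
  while (sprintf("R%d_11", n_links + 1L) %in% names(df)) n_links <- n_links + 1L
  if (n_links == 0L) {
    imu_stop(sprintf("malformed truth file %s: no DCM columns", path),
             "imujoint_bad_file")
  }
  N <- nrow(df)
  Rs <- lapply(seq_len(n_links), function(k) {
    A <- array(NA_real_, c(3L, 3L, N))
    for (r in 1:3) for (cc in 1:3) {
      A[r, cc, ] <- df[[sprintf("R%d_%d%d", k, r, cc)]]
    }
    A
  })
  list(time = df$t, R = Rs)
}

#' Write a joint-angle series to CSV
#'
#' Columns `t,alpha_deg,beta_deg,gamma_deg,flag`; `flag` is 0 (ok), 1
#' (constraint update skipped), 2 (gimbal-lock convention applied), 3 (both).
#'
#' @param angles A `joint_angles` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_angles_csv <- function(angles, path) {
  df <- data.frame(t = angles$t,
                   alpha_deg = rad2deg(angles$alpha),
                   beta_deg = rad2deg(angles$beta),
                   gamma_deg = rad2deg(angles$gamma),
                   flag = as.integer(angles$skipped) + 2L * as.integer(angles$gimbal))
  write_num_csv(df, path)
  invisible(path)
}

#' Read a joint-angle CSV
#'
#' @param path CSV written by [write_angles_csv()].
#' @return A `joint_angles` data frame (angles in radians; per-link yaw
#'   diagnostics absent are set to `NA`).
#' @export
read_angles_csv <- function(path) {
  df <- read_num_csv(path, c("t", "alpha_deg", "beta_deg", "gamma_deg", "flag"))
  structure(data.frame(t = df$t,
                       alpha = deg2rad(df$alpha_deg),
                       beta = deg2rad(df$beta_deg),
                       gamma = deg2rad(df$gamma_deg),
                       yaw_i = NA_real_, yaw_j = NA_real_,
                       skipped = bitwAnd(as.integer(df$flag), 1L) > 0L,
                       gimbal = bitwAnd(as.integer(df$flag), 2L) > 0L),
            class = c("joint_angles", "data.frame"))
}

#' Write an evaluation or calibration report as JSON
#'
#' @param report A named list (e.g. an `rmse_report` or
#'   `calibration_result`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Single YAML file with optional sections `sim`, `filter`, `calibration`,
#' `eval`; entries override the corresponding [sim_config()] /
#' [pipeline_config()] / [estimate_joint_vectors()] defaults.
#'
#' @param path YAML file path. `NULL` returns all defaults.
#' @return A list with elements `sim`, `filter`, `calibration`, `eval`
#'   (possibly empty lists).
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (sec in c("sim", "filter", "calibration", "eval")) {
    if (is.null(raw[[sec]])) raw[[sec]] <- list()
  }
  raw
}
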