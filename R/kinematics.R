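#' Estimate the calibration state from a stationary window
#'
#' Acquisition starts with the wrist resting in the calibration posture
#' (forearm pronated on the desk); the first `window_s` seconds are taken as
#' stationary and used to estimate the gyroscope bias and the gravity vector
#' in the sensor frame. All downstream angles are expressed relative to this
#' pose, which is defined as roll = pitch = yaw = 0.
#'
#' @param rec An [imu_recording()].
#' @param window_s Length of the stationary window at the start, seconds
#'   (default 1, minimum 0.5).
#' @param gyro_sd_max_dps If the per-axis gyro standard deviation inside the
#'   window exceeds this (deg/s) the window likely contains motion and the
#'   returned state is flagged `stationary = FALSE`.
#' @return A list of class `calibration_state` with `gyro_bias_dps`,
#'   `gravity_ref_mps2` (both length-3), `calib_time_s`, `stationary`, and
#'   `gravity_plausible` (gravity magnitude within 8.0--11.6 m/s^2).
#' @export
estimate_calibration <- function(rec, window_s = 1, gyro_sd_max_dps = 3) {
  stopifnot(inherits(rec, "imu_recording"))
  if (window_s < 0.5) stop("calibration window must be at least 0.5 s", call. = FALSE)
  keep <- rec$t_s < rec$t_s[1] + window_s
  if (sum(keep) < 2) stop("calibration window contains fewer than 2 samples", call. = FALSE)
  w <- rec[keep, ]
  gyro <- as.matrix(w[, c("gx_dps", "gy_dps", "gz_dps")])
  accel <- as.matrix(w[, c("ax_mps2", "ay_mps2", "az_mps2")])
  bias <- colMeans(gyro)
  gref <- colMeans(accel)
  gmag <- sqrt(sum(gref^2))
  out <- list(
    gyro_bias_dps = unname(bias),
    gravity_ref_mps2 = unname(gref),
    calib_time_s = w$t_s[nrow(w)],
    stationary = all(apply(gyro, 2, stats::sd) <= gyro_sd_max_dps),
    gravity_plausible = gmag >= 8.0 && gmag <= 11.6
  )
  class(out) <- "calibration_state"
  if (!out$stationary) {
    warning("calibration window appears to contain motion (gyro SD above ",
            gyro_sd_max_dps, " deg/s)", call. = FALSE)
  }
  out
}

#' @export
print.calibration_state <- function(x, ...) {
  cat(sprintf(
    "<calibration_state> gyro bias (%.3f, %.3f, %.3f) deg/s; gravity (%.2f, %.2f, %.2f) m/s^2%s%s\n",
    x$gyro_bias_dps[1], x$gyro_bias_dps[2], x$gyro_bias_dps[3],
    x$gravity_ref_mps2[1], x$gravity_ref_mps2[2], x$gravity_ref_mps2[3],
    if (!x$stationary) " [NOT stationary]" else "",
    if (!x$gravity_plausible) " [gravity magnitude implausible]" else ""
  ))
  invisible(x)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# rotation matrix exp(skew(theta)), theta in radians (Rodrigues)
rot_exp <- function(theta) {
  a <- sqrt(sum(theta^2))
  K <- skew3(theta)
  if (a < 1e-12) return(diag(3) + K)
  diag(3) + sin(a) / a * K + (1 - cos(a)) / a^2 * (K %*% K)
}

# intrinsic z-y-x (yaw, pitch, roll) Euler angles, radians, from body->frame R
euler_zyx <- function(R, prev_roll = 0) {
  sp <- -R[3, 1]
  sp <- max(-1, min(1, sp))
  pitch <- asin(sp)
  gimbal <- abs(sp) > sin(85 * pi / 180)
  if (!gimbal) {
    roll <- atan2(R[3, 2], R[3, 3])
    yaw <- atan2(R[2, 1], R[1, 1])
  } else {
    # near gimbal lock only yaw -/+ roll is observable; carry roll forward
    roll <- prev_roll
    if (sp > 0) yaw <- atan2(R[2, 3], R[2, 2]) + roll
    else yaw <- atan2(-R[2, 3], R[2, 2]) - roll
  }
  c(roll = roll, pitch = pitch, yaw = yaw, gimbal = gimbal)
}

unwrap_deg <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  x[1] + cumsum(c(0, d - 360 * round(d / 360)))
}

#' Integrate angular velocity into an orientation trace
#'
#' Strapdown reconstruction of the wrist attitude: the rotation from the
#' sensor body frame to the calibration frame is updated sample-to-sample by
#' the matrix exponential of the bias-corrected angular velocity over the
#' step, and intrinsic yaw-pitch-roll (z-y-x) Euler angles are extracted and
#' unwrapped. In the calibration posture roll tracks forearm
#' pronation/supination, pitch elbow flexion/extension, and yaw shoulder
#' internal/external rotation.
#'
#' @param rec A uniformly sampled [imu_recording()] (see [resample_uniform()]).
#' @param cal A `calibration_state` from [estimate_calibration()]; its gyro
#'   bias is subtracted before integration. Integration starts at the end of
#'   the calibration window with the identity attitude.
#' @return A tibble of class `orientation_trace` with columns `t_s`,
#'   `roll_deg`, `pitch_deg`, `yaw_deg`, `gimbal` (logical flag for samples
#'   within 5 degrees of pitch gimbal lock).
#' @export
integrate_orientation <- function(rec, cal) {
  stopifnot(inherits(rec, "imu_recording"), inherits(cal, "calibration_state"))
  if (nrow(rec) < 2) stop("need at least 2 samples", call. = FALSE)
  dt <- diff(rec$t_s)
  if (diff(range(dt)) > 1e-6 * stats::median(dt) + 1e-9) {
    stop("timestamps are not uniform; run resample_uniform() first", call. = FALSE)
  }
  gyro <- sweep(as.matrix(rec[, c("gx_dps", "gy_dps", "gz_dps")]), 2,
                cal$gyro_bias_dps) * pi / 180
  n <- nrow(rec)
  R <- diag(3)
  roll <- pitch <- yaw <- numeric(n)
  gimbal <- logical(n)
  prev_roll <- 0
  for (k in seq_len(n - 1)) {
    # first-order step: rate held over [k, k+1)
    R <- R %*% rot_exp(gyro[k, ] * dt[k])
    e <- euler_zyx(R, prev_roll)
    roll[k + 1] <- e[["roll"]]
    pitch[k + 1] <- e[["pitch"]]
    yaw[k + 1] <- e[["yaw"]]
    gimbal[k + 1] <- as.logical(e[["gimbal"]])
    prev_roll <- e[["roll"]]
  }
  out <- tibble::tibble(
    t_s = rec$t_s,
    roll_deg = unwrap_deg(roll * 180 / pi),
    pitch_deg = pitch * 180 / pi,  # asin range, cannot wrap
    yaw_deg = unwrap_deg(yaw * 180 / pi),
    gimbal = gimbal
  )
  class(out) <- c("orientation_trace", class(out))
  out
}

#' Acceleration channels in the calibration frame
#'
#' @param rec An [imu_recording()].
#' @param cal A `calibration_state`.
#' @param mode `"static_removed"` (default) subtracts the calibration gravity
#'   vector from each axis so the channels reflect movement-related
#'   acceleration; `"raw"` returns the sensor channels unchanged. The x and y
#'   axes are the planar directions of the calibration posture and z the
#'   vertical.
#' @return Tibble with columns `t_s`, `ax_mps2`, `ay_mps2`, `az_mps2`.
#' @export
calibrated_acceleration <- function(rec, cal, mode = c("static_removed", "raw")) {
  stopifnot(inherits(rec, "imu_recording"), inherits(cal, "calibration_state"))
  mode <- match.arg(mode)
  out <- tibble::as_tibble(rec[, c("t_s", "ax_mps2", "ay_mps2", "az_mps2")])
  if (mode == "static_removed") {
    out$ax_mps2 <- out$ax_mps2 - cal$gravity_ref_mps2[1]
    out$ay_mps2 <- out$ay_mps2 - cal$gravity_ref_mps2[2]
    out$az_mps2 <- out$az_mps2 - cal$gravity_ref_mps2[3]
  }
  out
}

#' Plot an orientation trace
#'
#' @param object An `orientation_trace`.
#' @param ... Unused.
#' @return A ggplot of the three Euler angles against time.
#' @method autoplot orientation_trace
#' @export
autoplot.orientation_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("roll_deg", "pitch_deg", "yaw_deg"),
                              names_to = "angle", values_to = "deg")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$deg, colour = .data$angle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "angle (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}
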