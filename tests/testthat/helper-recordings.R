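# build a uniform imu_recording from channel vectors (defaults: static, 25 Hz)
make_rec <- function(n = 100, rate = 25,
                     ax = 0, ay = 0, az = 9.81,
                     gx = 0, gy = 0, gz = 0, ...) {
  t <- (seq_len(n) - 1) / rate
  imu_recording(
    tibble::tibble(t_s = t,
                   ax_mps2 = rep_len(ax, n), ay_mps2 = rep_len(ay, n),
                   az_mps2 = rep_len(az, n),
                   gx_dps = rep_len(gx, n), gy_dps = rep_len(gy, n),
                   gz_dps = rep_len(gz, n)),
    ...
  )
}

# recording with a static calibration prefix followed by prescribed gyro
# rates; each sample's rate is held over the step to the next sample, so a
# trailing zero sample makes every prescribed rate take effect
rec_with_calib <- function(gx = 0, gy = 0, gz = 0, rate = 25, calib_s = 1) {
  n <- max(length(gx), length(gy), length(gz))
  gx <- rep_len(gx, n); gy <- rep_len(gy, n); gz <- rep_len(gz, n)
  nc <- calib_s * rate
  make_rec(n = nc + n + 1, rate = rate,
           gx = c(rep(0, nc), gx, 0), gy = c(rep(0, nc), gy, 0),
           gz = c(rep(0, nc), gz, 0))
}

# independent fine-step strapdown oracle: quaternion integration of
# body-frame angular velocity given as functions of time (rad/s)
quat_oracle <- function(wx_fun, wy_fun, wz_fun, t_end, dt) {
  q <- c(1, 0, 0, 0)
  qmul <- function(a, b) c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
  for (t in seq(0, t_end - dt, by = dt)) {
    w <- c(wx_fun(t), wy_fun(t), wz_fun(t))
    a <- sqrt(sum(w^2)) * dt
    axis <- if (a > 0) w / sqrt(sum(w^2)) else c(0, 0, 1)
    dq <- c(cos(a / 2), sin(a / 2) * axis)
    q <- qmul(q, dq)
    q <- q / sqrt(sum(q^2))
  }
  # quaternion -> rotation matrix -> z-y-x Euler (deg)
  w0 <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w0 * z), 2 * (x * z + w0 * y),
    2 * (x * y + w0 * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w0 * x),
    2 * (x * z - w0 * y), 2 * (y * z + w0 * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  c(roll = atan2(R[3, 2], R[3, 3]),
    pitch = asin(max(-1, min(1, -R[3, 1]))),
    yaw = atan2(R[2, 1], R[1, 1])) * 180 / pi
}
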