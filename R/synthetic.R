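#' Synthetic cohort settings
#'
#' Configuration of the synthetic IMU/score generator that emulates the
#' statistical structure the analysis assumes: per-subject impairment
#' severity `s` in \[0, 1\] drives (i) attenuation of movement amplitude
#' (factor `1 - 0.6 s`), (ii) growth of a band-limited oscillation that
#' fragments movements with extra direction reversals, (iii) slowing (task
#' duration grows by factor `1 + s`), and (iv) monotonically decreasing
#' clinical scores with integer noise, clipped to scale ranges.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param severity Optional numeric vector of per-subject severities in
#'   \[0, 1\]; default draws them uniformly.
#' @param rate_hz Sampling rate (default 25).
#' @param amplitude_map Named list per domain (`"1"`..`"4"`) of nominal
#'   angular excursions `c(roll=, pitch=, yaw=)` in degrees at severity 0.
#' @param displacement_map Per-domain nominal displacement excursions
#'   `c(x=, y=, z=)` in metres for the linked acceleration profile.
#' @param n_strokes Reach strokes per task recording (default 6).
#' @param stroke_duration_s Duration of one stroke at severity 0 (default 1.5).
#' @param tremor_freq_hz Centre of the oscillation band (default 4).
#' @param tremor_amp_deg Oscillation amplitude at severity 1 (default 0.5).
#'   At the default band this puts the peak tremor angular rate
#'   (`2 * pi * f * a` ~ 12.6 deg/s) on par with the slowest gross-movement
#'   sweep rate, so the oscillation fragments sweep endpoints and erodes
#'   segment sizes monotonically with severity; much larger values make
#'   tremor reversals dominate segmentation outright, and the
#'   threshold-filtered average then no longer decreases with impairment.
#' @param gyro_noise_dps,accel_noise_mps2 White measurement noise SDs.
#' @param gyro_bias_dps Half-width of the uniform per-recording gyro bias.
#' @param score_noise_sd SD of the integer noise added to generated scores.
#' @param calib_window_s Static calibration prefix prepended to every
#'   recording (default 1 s), emulating the button-press calibration pause.
#' @param followup Generate a follow-up session per subject?
#' @param followup_improvement Relative severity reduction at follow-up
#'   (default 0.3, i.e. `s_followup = 0.7 s_baseline`).
#' @param seed Integer seed; one global seed fans out to per-recording
#'   substreams.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 20,
                             severity = NULL,
                             rate_hz = 25,
                             amplitude_map = list(
                               `1` = c(roll = 15, pitch = 30, yaw = 10),
                               `2` = c(roll = 10, pitch = 25, yaw = 15),
                               `3` = c(roll = 10, pitch = 20, yaw = 8),
                               `4` = c(roll = 45, pitch = 40, yaw = 60)),
                             displacement_map = list(
                               `1` = c(x = 0.25, y = 0.10, z = 0.10),
                               `2` = c(x = 0.30, y = 0.20, z = 0.05),
                               `3` = c(x = 0.20, y = 0.10, z = 0.08),
                               `4` = c(x = 0.15, y = 0.15, z = 0.40)),
                             n_strokes = 6,
                             stroke_duration_s = 1.5,
                             tremor_freq_hz = 4,
                             tremor_amp_deg = 0.5,
                             gyro_noise_dps = 0.5,
                             accel_noise_mps2 = 0.02,
                             gyro_bias_dps = 0.5,
                             score_noise_sd = 2,
                             calib_window_s = 1,
                             followup = FALSE,
                             followup_improvement = 0.3,
                             seed = 1L) {
  if (!is.null(severity)) {
    stopifnot(all(severity >= 0 & severity <= 1))
    n_subjects <- length(severity)
  }
  stopifnot(rate_hz > 0, n_subjects >= 1, n_strokes >= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

# minimum-jerk unit stroke: position 0 -> 1 over tau in [0,1], with
# velocity and acceleration (per unit time and time^2)
minjerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  list(pos = 10 * tau^3 - 15 * tau^4 + 6 * tau^5,
       vel = 30 * tau^2 - 60 * tau^3 + 30 * tau^4,
       acc = 60 * tau - 180 * tau^2 + 120 * tau^3)
}

# alternating 0 -> 1 -> 0 ... stroke train sampled at t (seconds from train
# start); returns unit position/velocity/acceleration
stroke_train <- function(t, n_strokes, stroke_T) {
  k <- pmin(floor(t / stroke_T), n_strokes - 1)           # stroke index
  tau <- (t - k * stroke_T) / stroke_T
  tau[t >= n_strokes * stroke_T] <- 1
  mj <- minjerk(tau)
  up <- k %% 2 == 0                                        # even strokes go up
  list(pos = ifelse(up, mj$pos, 1 - mj$pos),
       vel = ifelse(up, mj$vel, -mj$vel) / stroke_T,
       acc = ifelse(up, mj$acc, -mj$acc) / stroke_T^2)
}

# intrinsic z-y-x Euler angle rates (rad/s) -> body angular rates (rad/s)
euler_rates_to_body <- function(roll, pitch, rd, pd, yd) {
  cbind(rd - yd * sin(pitch),
        pd * cos(roll) + yd * cos(pitch) * sin(roll),
        -pd * sin(roll) + yd * cos(pitch) * cos(roll))
}

#' Generate one synthetic task-domain recording
#'
#' Builds an analytic wrist trajectory -- a train of minimum-jerk reach
#' strokes per Euler axis, attenuated and slowed by severity, superposed with
#' a severity-scaled oscillation that introduces direction reversals -- and
#' emits the corresponding IMU channels: body angular rates via the exact
#' Euler-rate kinematics plus bias and noise, and accelerometer channels from
#' the second derivative of a linked displacement profile plus constant
#' gravity `(0, 0, 9.81)` and noise. A static calibration window is
#' prepended.
#'
#' @param domain Task domain 1..4.
#' @param severity Impairment severity in \[0, 1\].
#' @param config A [synthetic_config()].
#' @param seed Integer seed for this recording's noise and phases.
#' @param subject_id,session,wrist_side,affected Metadata for the returned
#'   recording.
#' @return An [imu_recording()] with an attribute `true_amplitude_deg`
#'   (named roll/pitch/yaw severity-attenuated stroke amplitudes, the
#'   construction ground truth).
#' @export
generate_task_trace <- function(domain, severity, config = synthetic_config(),
                                seed = config$seed, subject_id = "sim",
                                session = "baseline", wrist_side = "right",
                                affected = TRUE) {
  domain <- as.character(domain)
  if (!domain %in% c("1", "2", "3", "4")) {
    stop("`domain` must be 1..4, got ", domain, call. = FALSE)
  }
  stopifnot(severity >= 0, severity <= 1)
  set.seed(seed)
  rate <- config$rate_hz
  amp <- config$amplitude_map[[domain]] * (1 - 0.6 * severity)
  disp <- config$displacement_map[[domain]] * (1 - 0.6 * severity)
  stroke_T <- config$stroke_duration_s * (1 + severity)
  move_T <- config$n_strokes * stroke_T
  t <- seq(0, config$calib_window_s + move_T, by = 1 / rate)
  tm <- pmax(t - config$calib_window_s, 0)                 # time since movement onset
  moving <- t > config$calib_window_s

  # oscillatory fragmentation: two tones around the band centre, ramped on
  # over the first second of movement
  f1 <- config$tremor_freq_hz * stats::runif(1, 0.9, 1.1)
  f2 <- config$tremor_freq_hz * stats::runif(1, 1.3, 1.7)
  ph <- stats::runif(6, 0, 2 * pi)
  env <- pmin(tm, 1) * moving
  denv <- as.numeric(tm < 1 & moving)
  trem_amp <- severity * config$tremor_amp_deg
  tremor <- function(i) {
    a1 <- sin(2 * pi * f1 * tm + ph[i]); a2 <- 0.5 * sin(2 * pi * f2 * tm + ph[i + 3])
    d1 <- 2 * pi * f1 * cos(2 * pi * f1 * tm + ph[i])
    d2 <- 0.5 * 2 * pi * f2 * cos(2 * pi * f2 * tm + ph[i + 3])
    list(pos = trem_amp * env * (a1 + a2),
         vel = trem_amp * (denv * (a1 + a2) + env * (d1 + d2)) * moving)
  }

  train <- stroke_train(tm, config$n_strokes, stroke_T)
  train$pos[!moving] <- 0; train$vel[!moving] <- 0; train$acc[!moving] <- 0
  ax_names <- c("roll", "pitch", "yaw")
  ang <- vel <- list()
  for (i in 1:3) {
    tr <- tremor(i)
    ang[[i]] <- amp[[ax_names[i]]] * train$pos + tr$pos    # deg
    vel[[i]] <- amp[[ax_names[i]]] * train$vel + tr$vel    # deg/s
  }
  gyro_body <- euler_rates_to_body(
    ang[[1]] * pi / 180, ang[[2]] * pi / 180,
    vel[[1]] * pi / 180, vel[[2]] * pi / 180, vel[[3]] * pi / 180
  ) * 180 / pi
  bias <- stats::runif(3, -config$gyro_bias_dps, config$gyro_bias_dps)
  n <- length(t)
  gyro <- gyro_body +
    matrix(stats::rnorm(3 * n, 0, config$gyro_noise_dps), n, 3) +
    matrix(bias, n, 3, byrow = TRUE)

  lin <- sapply(c("x", "y", "z"), function(a) disp[[a]] * train$acc)
  accel <- lin + matrix(c(0, 0, 9.81), n, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * n, 0, config$accel_noise_mps2), n, 3)

  rec <- imu_recording(
    tibble::tibble(t_s = t,
                   ax_mps2 = accel[, 1], ay_mps2 = accel[, 2], az_mps2 = accel[, 3],
                   gx_dps = gyro[, 1], gy_dps = gyro[, 2], gz_dps = gyro[, 3]),
    subject_id = subject_id, wrist_side = wrist_side, affected = affected,
    domain = domain, session = session, nominal_rate_hz = rate
  )
  attr(rec, "true_amplitude_deg") <- amp
  rec
}

#' Generate a synthetic cohort of recordings and clinical scores
#'
#' One affected-wrist recording per subject and task domain (and per session
#' when `followup = TRUE`, with severity reduced by the configured
#' improvement), plus a clinical record per subject/session whose ARAT, FMUE
#' and MBI decrease monotonically with severity before integer noise and
#' clipping to scale ranges.
#'
#' @param config A [synthetic_config()].
#' @return List with `recordings` (list of [imu_recording()]) and `scores`
#'   (tibble in the [load_scores()] layout, plus a `severity` column).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  severity <- config$severity %||% stats::runif(n)
  sessions <- if (config$followup) c("baseline", "followup") else "baseline"
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1, n * length(sessions) * 4),
                      nrow = n)
  ages <- pmin(pmax(round(stats::rnorm(n, 62, 14)), 30), 90)
  sexes <- sample(c("M", "F"), n, replace = TRUE)
  onset <- round(stats::rlnorm(n, log(60), 0.9))
  sides <- sample(c("left", "right"), n, replace = TRUE)

  score_of <- function(s, max) {
    as.integer(pmin(pmax(round(max * (1 - s)) +
                           round(stats::rnorm(length(s), 0, config$score_noise_sd)),
                         0), max))
  }
  recordings <- list()
  scores <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("sim%02d", i)
    for (j in seq_along(sessions)) {
      sess <- sessions[j]
      s <- if (sess == "baseline") severity[i] else
        severity[i] * (1 - config$followup_improvement)
      for (d in 1:4) {
        recordings[[length(recordings) + 1L]] <- generate_task_trace(
          domain = d, severity = s, config = config,
          seed = sub_seeds[i, (j - 1) * 4 + d],
          subject_id = sid, session = sess, wrist_side = sides[i]
        )
      }
      scores[[length(scores) + 1L]] <- tibble::tibble(
        subject_id = sid, age = ages[i], sex = sexes[i],
        diagnosis = "synthetic", days_since_onset = onset[i],
        hemiplegic_side = sides[i], session = sess,
        arat = score_of(s, 57), mbi = score_of(s, 100), fmue = score_of(s, 66),
        severity = s
      )
    }
  }
  list(recordings = recordings, scores = dplyr::bind_rows(scores))
}
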