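#' Construct a wrist IMU recording
#'
#' An `imu_recording` is a tibble of timestamped tri-axial accelerometer and
#' gyroscope samples from one wrist during one task window, with the recording
#' metadata (subject, wrist side, affected flag, ARAT task domain, session,
#' nominal sampling rate) carried as attributes. Columns:
#' `t_s` (seconds, strictly increasing), `ax_mps2`, `ay_mps2`, `az_mps2`
#' (m/s^2, sensor frame), `gx_dps`, `gy_dps`, `gz_dps` (deg/s, sensor frame).
#'
#' @param data Data frame with the seven columns above.
#' @param subject_id Opaque subject label.
#' @param wrist_side `"left"` or `"right"`.
#' @param affected Logical; is this the hemiparetic side?
#' @param domain ARAT task domain: `"1"`..`"4"` or `"whole"`.
#' @param session `"baseline"` or `"followup"`.
#' @param nominal_rate_hz Nominal sampling rate in Hz (> 0).
#'
#' @return A tibble of class `imu_recording`.
#' @export
#' @examples
#' imu_recording(
#'   tibble::tibble(t_s = c(0, 0.04, 0.08),
#'                  ax_mps2 = 0, ay_mps2 = 0, az_mps2 = 9.81,
#'                  gx_dps = 0, gy_dps = 0, gz_dps = 0),
#'   subject_id = "S1", wrist_side = "right", affected = TRUE, domain = "1"
#' )
imu_recording <- function(data,
                          subject_id = "unknown",
                          wrist_side = c("right", "left"),
                          affected = TRUE,
                          domain = "whole",
                          session = "baseline",
                          nominal_rate_hz = 25) {
  wrist_side <- match.arg(wrist_side)
  domain <- as.character(domain)
  if (!domain %in% c("1", "2", "3", "4", "whole")) {
    stop("`domain` must be one of \"1\"..\"4\" or \"whole\", got ", domain,
         call. = FALSE)
  }
  if (!session %in% c("baseline", "followup")) {
    stop("`session` must be \"baseline\" or \"followup\"", call. = FALSE)
  }
  if (!is.numeric(nominal_rate_hz) || nominal_rate_hz <= 0) {
    stop("`nominal_rate_hz` must be a positive number", call. = FALSE)
  }
  cols <- imu_channel_cols()
  missing <- setdiff(c("t_s", cols), names(data))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data[, c("t_s", cols)])
  dt <- diff(out$t_s)
  if (length(dt) && any(dt <= 0)) {
    stop("timestamps must be strictly increasing; first violation at index ",
         which(dt <= 0)[1] + 1L, call. = FALSE)
  }
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "wrist_side") <- wrist_side
  attr(out, "affected") <- isTRUE(affected)
  attr(out, "domain") <- domain
  attr(out, "session") <- session
  attr(out, "nominal_rate_hz") <- as.numeric(nominal_rate_hz)
  class(out) <- c("imu_recording", class(tibble::tibble()))
  out
}

imu_channel_cols <- function() {
  c("ax_mps2", "ay_mps2", "az_mps2", "gx_dps", "gy_dps", "gz_dps")
}

#' Recording metadata
#'
#' @param rec An [imu_recording()].
#' @return One-row tibble of the recording metadata plus sample count and
#'   duration in seconds.
#' @export
imu_meta <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  tibble::tibble(
    subject_id = attr(rec, "subject_id"),
    wrist_side = attr(rec, "wrist_side"),
    affected = attr(rec, "affected"),
    domain = attr(rec, "domain"),
    session = attr(rec, "session"),
    nominal_rate_hz = attr(rec, "nominal_rate_hz"),
    n_samples = nrow(rec),
    duration_s = if (nrow(rec)) rec$t_s[nrow(rec)] - rec$t_s[1] else 0
  )
}

# rebuild an imu_recording from new sample data, keeping rec's metadata
imu_like <- function(rec, data, domain = attr(rec, "domain")) {
  imu_recording(
    data,
    subject_id = attr(rec, "subject_id"),
    wrist_side = attr(rec, "wrist_side"),
    affected = attr(rec, "affected"),
    domain = domain,
    session = attr(rec, "session"),
    nominal_rate_hz = attr(rec, "nominal_rate_hz")
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  m <- imu_meta(x)
  cat(sprintf(
    "<imu_recording> subject %s, %s wrist%s, domain %s, %s\n  %d samples, %.2f s @ %g Hz nominal\n",
    m$subject_id, m$wrist_side, if (m$affected) " (affected)" else "",
    m$domain, m$session, m$n_samples, m$duration_s, m$nominal_rate_hz
  ))
  NextMethod()
}
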