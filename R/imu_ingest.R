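#' Read a wrist IMU recording from CSV
#'
#' The on-disk format is a plain CSV with metadata header lines of the form
#' `# key: value` (subject_id, wrist_side, affected, domain, session,
#' nominal_rate_hz) followed by a header row and the sample columns
#' `t_s, ax_mps2, ay_mps2, az_mps2, gx_dps, gy_dps, gz_dps`. A `schema` map
#' can rename columns and rescale units from loggers that record g or rad/s.
#'
#' @param path File path.
#' @param schema Optional named list mapping canonical column names to the
#'   file's column names, plus optional `accel_scale` and `gyro_scale`
#'   multiplicative factors applied to convert the file's units to m/s^2 and
#'   deg/s (e.g. `accel_scale = 9.80665` for data logged in g).
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  meta <- parse_meta_lines(header)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  canon <- c("t_s", imu_channel_cols())
  file_names <- canon
  if (!is.null(schema)) {
    for (nm in intersect(names(schema), canon)) file_names[canon == nm] <- schema[[nm]]
  }
  missing <- setdiff(file_names, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  df <- df[, file_names]
  names(df) <- canon
  a_scale <- if (!is.null(schema$accel_scale)) schema$accel_scale else 1
  g_scale <- if (!is.null(schema$gyro_scale)) schema$gyro_scale else 1
  df[c("ax_mps2", "ay_mps2", "az_mps2")] <- df[c("ax_mps2", "ay_mps2", "az_mps2")] * a_scale
  df[c("gx_dps", "gy_dps", "gz_dps")] <- df[c("gx_dps", "gy_dps", "gz_dps")] * g_scale
  imu_recording(
    df,
    subject_id = meta$subject_id %||% "unknown",
    wrist_side = meta$wrist_side %||% "right",
    affected = as.logical(meta$affected %||% TRUE),
    domain = meta$domain %||% "whole",
    session = meta$session %||% "baseline",
    nominal_rate_hz = as.numeric(meta$nominal_rate_hz %||% 25)
  )
}

parse_meta_lines <- function(lines) {
  out <- list()
  for (line in lines) {
    m <- regmatches(line, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", line))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Write a wrist IMU recording to CSV
#'
#' Inverse of [read_imu_csv()]: metadata as `# key: value` comment lines,
#' then the sample table.
#'
#' @param rec An [imu_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  m <- imu_meta(rec)
  hdr <- sprintf("# %s: %s",
                 c("subject_id", "wrist_side", "affected", "domain",
                   "session", "nominal_rate_hz"),
                 c(m$subject_id, m$wrist_side, m$affected, m$domain,
                   m$session, format(m$nominal_rate_hz)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(rec), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Resample a recording onto a uniform time grid
#'
#' The smartwatch logger delivers samples at a 25 Hz *average* rate with
#' jitter; orientation integration and first differencing assume a uniform
#' step, so recordings are linearly interpolated onto an arithmetic grid
#' spanning the original time range before kinematics.
#'
#' @param rec An [imu_recording()] with at least 2 samples.
#' @param rate_hz Target rate in Hz (default 25).
#' @return A uniformly sampled [imu_recording()].
#' @export
resample_uniform <- function(rec, rate_hz = 25) {
  stopifnot(inherits(rec, "imu_recording"))
  if (nrow(rec) < 2) stop("resampling needs at least 2 samples", call. = FALSE)
  if (rate_hz <= 0) stop("`rate_hz` must be positive", call. = FALSE)
  t0 <- rec$t_s[1]
  t1 <- rec$t_s[nrow(rec)]
  grid <- t0 + seq(0, floor((t1 - t0) * rate_hz)) / rate_hz
  data <- tibble::tibble(t_s = grid)
  for (col in imu_channel_cols()) {
    data[[col]] <- stats::approx(rec$t_s, rec[[col]], xout = grid)$y
  }
  out <- imu_like(rec, data)
  attr(out, "nominal_rate_hz") <- as.numeric(rate_hz)
  out
}

#' Split a session recording into ARAT task-domain windows
#'
#' @param rec An [imu_recording()].
#' @param annotations Data frame with columns `domain` (1..4), `start_s`,
#'   `end_s`; windows are half-open `[start_s, end_s)` so a boundary sample
#'   is never assigned twice.
#' @return A list of [imu_recording()]s, one per annotation row, with the
#'   `domain` attribute set.
#' @export
split_by_domain <- function(rec, annotations) {
  stopifnot(inherits(rec, "imu_recording"))
  req <- c("domain", "start_s", "end_s")
  if (!all(req %in% names(annotations))) {
    stop("annotations need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(annotations$start_s >= annotations$end_s)) {
    stop("annotation windows must have start_s < end_s", call. = FALSE)
  }
  purrr::pmap(annotations[req], function(domain, start_s, end_s) {
    keep <- rec$t_s >= start_s & rec$t_s < end_s
    if (!any(keep)) {
      stop(sprintf("annotation [%g, %g) for domain %s lies outside the recording",
                   start_s, end_s, domain), call. = FALSE)
    }
    imu_like(rec, rec[keep, , drop = FALSE], domain = as.character(domain))
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
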