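#' MSS computation settings
#'
#' @param angle_threshold_deg Segments of angular signals must exceed this
#'   size (strictly) to enter the average; default 10 degrees.
#' @param accel_threshold_mps2 Threshold for acceleration signals; default
#'   0.05 m/s^2.
#' @param plateau `"extend"` (default): runs of zero first difference do not
#'   end a segment -- a pause is not a direction change; `"break"`: plateaus
#'   terminate the segment and form their own zero-size segments.
#' @param smooth_window Optional odd integer; centred moving-average window
#'   (in samples) applied before segmentation. `NULL` (default) applies no
#'   smoothing.
#' @return A list of class `mss_config`.
#' @export
mss_config <- function(angle_threshold_deg = 10,
                       accel_threshold_mps2 = 0.05,
                       plateau = c("extend", "break"),
                       smooth_window = NULL) {
  plateau <- match.arg(plateau)
  stopifnot(angle_threshold_deg > 0, accel_threshold_mps2 > 0)
  if (!is.null(smooth_window)) {
    stopifnot(smooth_window >= 1, smooth_window %% 2 == 1)
  }
  structure(list(angle_threshold_deg = angle_threshold_deg,
                 accel_threshold_mps2 = accel_threshold_mps2,
                 plateau = plateau,
                 smooth_window = smooth_window),
            class = "mss_config")
}

moving_average <- function(x, k) {
  if (is.null(k) || k <= 1) return(x)
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  # shrink the window at the edges instead of dropping samples
  h <- (k - 1) / 2
  n <- length(x)
  for (i in which(is.na(sm))) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    sm[i] <- mean(x[lo:hi])
  }
  as.numeric(sm)
}

#' Segment a signal at direction reversals
#'
#' A motion segment is a maximal run over which the signal moves in one
#' direction (the sign of the first difference is constant); its size is the
#' total variation over the run, `sum(|x[t] - x[t-1]|)`, which for a monotone
#' run equals the net excursion. Boundaries fall at discrete zero crossings
#' of the derivative; segments at the start and end of the recording are kept
#' and thresholded like any other. Adjacent segments share the extremum
#' sample at which the direction reverses, so every first difference belongs
#' to exactly one segment and the segment sizes sum exactly to the signal's
#' total variation.
#'
#' @param values Numeric vector, at least 2 samples.
#' @param plateau Zero-difference handling, see [mss_config()].
#' @param smooth_window Optional pre-smoothing window, see [mss_config()].
#' @return Tibble with one row per segment: `start_idx`, `end_idx` (1-based
#'   inclusive sample indices of the monotone run), `size` (signal units).
#' @export
#' @examples
#' segment_signal(c(0, 10, 20, 10, 0, 10, 20))  # triangle: 3 segments of 20
segment_signal <- function(values, plateau = c("extend", "break"),
                           smooth_window = NULL) {
  plateau <- match.arg(plateau)
  if (length(values) < 2) stop("need at least 2 samples to segment", call. = FALSE)
  values <- moving_average(values, smooth_window)
  d <- diff(values)
  s <- sign(d)
  if (plateau == "extend") {
    # zeros take the sign of the previous non-zero difference (a pause
    # continues the ongoing segment); leading zeros join the first move
    nz <- s != 0
    if (any(nz)) {
      idx <- cumsum(nz)
      filled <- c(s[nz][1], s[nz])[idx + 1]  # leading zeros -> first sign
      s <- filled
    }
  }
  r <- rle(s)
  ends <- cumsum(r$lengths)        # diff indices
  starts <- c(1L, utils::head(ends, -1) + 1L)
  sizes <- vapply(seq_along(ends),
                  function(i) sum(abs(d[starts[i]:ends[i]])), numeric(1))
  tibble::tibble(start_idx = starts, end_idx = ends + 1L, size = sizes)
}

#' Average motion segment size above a threshold
#'
#' The headline statistic: the arithmetic mean of the segment sizes strictly
#' exceeding the threshold. Small sub-threshold segments (tremor, noise) are
#' excluded; when no segment qualifies the average is undefined and `NA` is
#' returned (never zero), and such cells are dropped pairwise downstream.
#'
#' @param sizes Numeric vector of segment sizes (from [segment_signal()]).
#' @param threshold Positive threshold in the signal's units.
#' @return Scalar mean of qualifying sizes, or `NA_real_` if none qualify.
#' @export
average_mss <- function(sizes, threshold) {
  stopifnot(threshold > 0)
  keep <- sizes > threshold
  if (!any(keep)) return(NA_real_)
  mean(sizes[keep])
}

#' Task performance time
#'
#' @param x An [imu_recording()], `orientation_trace`, or numeric timestamp
#'   vector.
#' @return Elapsed time `last - first` in seconds.
#' @export
performance_time <- function(x) {
  t_s <- if (is.numeric(x)) x else x$t_s
  if (length(t_s) < 2) stop("need at least 2 samples", call. = FALSE)
  t_s[length(t_s)] - t_s[1]
}

#' Compute MSS results for all six kinematic signals
#'
#' Applies [segment_signal()] and [average_mss()] to the three
#' calibration-frame acceleration channels (threshold 0.05 m/s^2) and the
#' three Euler angles (threshold 10 degrees) of one task recording.
#'
#' @param orient An `orientation_trace` from [integrate_orientation()].
#' @param accel Acceleration tibble from [calibrated_acceleration()].
#' @param config An [mss_config()].
#' @param keep_segments If `TRUE`, include a list-column `sizes` with every
#'   segment size (needed to pool domains into whole-test statistics).
#' @return Tibble with one row per signal: `signal`, `threshold`,
#'   `n_segments`, `n_above_threshold`, `average_mss`, `performance_time_s`.
#' @export
compute_mss <- function(orient, accel, config = mss_config(),
                        keep_segments = FALSE) {
  stopifnot(inherits(config, "mss_config"))
  signals <- list(
    accel_x = list(values = accel$ax_mps2, threshold = config$accel_threshold_mps2),
    accel_y = list(values = accel$ay_mps2, threshold = config$accel_threshold_mps2),
    accel_z = list(values = accel$az_mps2, threshold = config$accel_threshold_mps2),
    roll = list(values = orient$roll_deg, threshold = config$angle_threshold_deg),
    pitch = list(values = orient$pitch_deg, threshold = config$angle_threshold_deg),
    yaw = list(values = orient$yaw_deg, threshold = config$angle_threshold_deg)
  )
  pt <- performance_time(orient$t_s)
  out <- purrr::imap(signals, function(sg, label) {
    seg <- segment_signal(sg$values, plateau = config$plateau,
                          smooth_window = config$smooth_window)
    row <- tibble::tibble(
      signal = label,
      threshold = sg$threshold,
      n_segments = nrow(seg),
      n_above_threshold = sum(seg$size > sg$threshold),
      average_mss = average_mss(seg$size, sg$threshold),
      performance_time_s = pt
    )
    if (keep_segments) row$sizes <- list(seg$size)
    row
  })
  dplyr::bind_rows(out)
}

#' Plot segment sizes of a signal
#'
#' @param values Numeric signal.
#' @param threshold Qualifying threshold drawn as a dashed line.
#' @param ... Passed to [segment_signal()].
#' @return A ggplot: signal trace with segment boundaries and a bar panel of
#'   segment sizes.
#' @export
plot_segments <- function(values, threshold = NULL, ...) {
  seg <- segment_signal(values, ...)
  df <- tibble::tibble(idx = seq_along(values), value = values)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$idx, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = seg$end_idx[-nrow(seg)],
                        linetype = "dotted", colour = "grey50") +
    ggplot2::labs(x = "sample", y = "signal") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::labs(
      subtitle = sprintf("%d of %d segments exceed the threshold (%g)",
                         sum(seg$size > threshold), nrow(seg), threshold))
  }
  p
}
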