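test_that("a monotone ramp is a single segment with its net excursion", {
  seg <- segment_signal(seq(0, 30, by = 2))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$size, 30)
  expect_equal(seg$start_idx, 1)
  expect_equal(seg$end_idx, 16)
  expect_error(segment_signal(5), "at least 2")
})

test_that("a triangle wave splits into per-leg segments", {
  tri <- c(0, 10, 20, 10, 0, 10, 20)
  seg <- segment_signal(tri)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$size, c(20, 20, 20))
  # every first difference is covered exactly once
  expect_equal(seg$start_idx[-1], seg$end_idx[-3])
})

test_that("plateaus extend the running segment by default but can break it", {
  x <- c(0, 5, 5, 5, 10, 5, 0)
  ext <- segment_signal(x, plateau = "extend")
  expect_equal(ext$size, c(10, 10))
  brk <- segment_signal(x, plateau = "break")
  expect_equal(brk$size, c(5, 0, 5, 10))
  # an all-constant signal is one zero-size segment either way
  expect_equal(segment_signal(rep(3, 10))$size, 0)
})

test_that("interior segments of a sampled sinusoid have size 2A", {
  A <- 30
  t <- seq(0, 2, by = 1 / 250)  # dense sampling, f = 2 Hz
  seg <- segment_signal(A * sin(2 * pi * 2 * t))
  interior <- seg[-c(1, nrow(seg)), ]
  step_err <- 2 * A * (2 * pi * 2 / 250)  # one-sample discretization bound
  expect_true(all(abs(interior$size - 2 * A) < step_err))
  expect_true(all(seg$size[c(1, nrow(seg))] <= A + step_err))
  # cross-check interior sizes against brute-force total variation between
  # the sampled extrema
  x <- A * sin(2 * pi * 2 * t)
  for (i in seq_len(nrow(interior))) {
    run <- x[interior$start_idx[i]:interior$end_idx[i]]
    expect_equal(interior$size[i], sum(abs(diff(run))))
  }
})

test_that("segment sizes always sum to the signal's total variation", {
  set.seed(21)
  for (rep in 1:20) {
    x <- cumsum(rnorm(sample(10:200, 1)))
    for (pol in c("extend", "break")) {
      seg <- segment_signal(x, plateau = pol)
      expect_equal(sum(seg$size), sum(abs(diff(x))))
    }
  }
  # integer-valued signal with genuine plateaus
  y <- rep(c(0, 2, 2, 5, 3, 3, 3, 8), 4)
  expect_equal(sum(segment_signal(y)$size), sum(abs(diff(y))))
  expect_equal(sum(segment_signal(y, plateau = "break")$size), sum(abs(diff(y))))
})

test_that("refining a piecewise-monotone signal leaves segment sizes unchanged", {
  x <- c(0, 20, 5, 30, 10)
  refined <- c(0, 7, 13, 20, 15, 9, 5, 14, 22, 30, 24, 17, 10)
  expect_equal(segment_signal(refined)$size, segment_signal(x)$size)
})

test_that("average MSS filters strictly above threshold and is NA when empty", {
  expect_equal(average_mss(c(30, 5, 12), 10), 21)
  expect_true(is.na(average_mss(c(4, 7), 10)))
  # boundary: exactly-at-threshold segments do not qualify
  expect_true(is.na(average_mss(c(10, 10), 10)))
  expect_error(average_mss(c(1, 2), -1))
  # brute-force filter-then-mean oracle on random segment lists
  set.seed(5)
  for (i in 1:50) {
    sizes <- runif(sample(1:30, 1), 0, 40)
    thr <- runif(1, 1, 20)
    oracle <- if (sum(sizes > thr) == 0) NA_real_ else {
      tot <- 0; k <- 0
      for (s in sizes) if (s > thr) { tot <- tot + s; k <- k + 1 }
      tot / k
    }
    expect_equal(average_mss(sizes, thr), oracle)
  }
})

test_that("threshold monotonicity and amplitude equivariance hold", {
  set.seed(31)
  x <- cumsum(rnorm(300))
  seg <- segment_signal(x)
  thresholds <- seq(0.1, 5, by = 0.1)
  counts <- vapply(thresholds, function(th) sum(seg$size > th), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # scaling signal and threshold by c > 0 scales the average by c
  c_ <- 3.7
  seg_scaled <- segment_signal(c_ * x)
  expect_equal(seg_scaled$size, c_ * seg$size)
  expect_equal(average_mss(seg_scaled$size, c_ * 1.5),
               c_ * average_mss(seg$size, 1.5))
})

test_that("performance time is the elapsed recording span", {
  expect_equal(performance_time(c(0, 50, 96.3)), 96.3)
  expect_equal(performance_time(make_rec(n = 100, rate = 25)), 99 / 25)
  expect_error(performance_time(3), "at least 2")
  # domain windows partition the whole-test time when gaps are excluded
  rec <- make_rec(n = 400, rate = 25)
  ann <- tibble::tibble(domain = 1:4, start_s = c(0, 4, 8, 12),
                        end_s = c(4, 8, 12, 16))
  parts <- split_by_domain(rec, ann)
  per_domain <- vapply(parts, performance_time, numeric(1))
  # half-open windows: each domain spans its window minus one sample step
  expect_equal(sum(per_domain) + 4 / 25, 16, tolerance = 1e-12)
})

test_that("compute_mss applies the label-appropriate thresholds", {
  n <- 101
  t <- (0:(n - 1)) / 25
  # cosines start and end on sampled extrema, so every segment is a full
  # peak-to-peak excursion of size 2A
  orient <- tibble::tibble(
    t_s = t,
    roll_deg = 30 * cos(2 * pi * 0.5 * t),   # segments of 60 deg
    pitch_deg = 2 * cos(2 * pi * 0.5 * t),   # below the 10 deg threshold
    yaw_deg = rep(0, n),
    gimbal = FALSE
  )
  class(orient) <- c("orientation_trace", class(orient))
  accel <- tibble::tibble(
    t_s = t,
    ax_mps2 = 0.5 * cos(2 * pi * 1 * t),     # segments of ~1 m/s^2
    ay_mps2 = 0.01 * cos(2 * pi * 1 * t),    # below 0.05 m/s^2
    az_mps2 = rep(0, n)
  )
  res <- compute_mss(orient, accel)
  expect_equal(res$signal,
               c("accel_x", "accel_y", "accel_z", "roll", "pitch", "yaw"))
  get <- function(sig) res$average_mss[res$signal == sig]
  expect_equal(get("roll"), 60, tolerance = 0.05)
  expect_true(is.na(get("pitch")))
  expect_true(is.na(get("yaw")))
  expect_equal(get("accel_x"), 1, tolerance = 0.05)
  expect_true(is.na(get("accel_y")))
  expect_true(all(res$performance_time_s == t[n]))
  expect_equal(res$threshold, c(0.05, 0.05, 0.05, 10, 10, 10))
})

test_that("pre-smoothing suppresses noise-induced reversals", {
  set.seed(13)
  t <- (0:499) / 25
  x <- 30 * cos(2 * pi * 0.25 * t) + rnorm(500, 0, 0.5)
  raw <- segment_signal(x)
  smoothed <- segment_signal(x, smooth_window = 5)
  expect_lt(nrow(smoothed), nrow(raw))
  expect_equal(average_mss(smoothed$size, 10), 60, tolerance = 0.1)
})
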