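test_that("Spearman on the pooled cohort scores reproduces the published coefficients", {
  scores <- load_scores(wristmss_example("table1_scores.csv"))
  fmue <- spearman_cor(scores$arat, scores$fmue)
  mbi <- spearman_cor(scores$arat, scores$mbi)
  expect_equal(fmue$n, 13)
  expect_equal(round(fmue$rs, 3), 0.938)
  expect_equal(round(mbi$rs, 3), 0.812)
  expect_lt(fmue$p_value, 0.001)
  expect_lt(mbi$p_value, 0.001)
})

test_that("spearman_cor agrees with the reference implementation", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    x <- sample(1:10, n, replace = TRUE)  # ties likely
    y <- x + rnorm(n, 0, 3)
    got <- spearman_cor(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = FALSE))
    expect_equal(got$rs, unname(ref$estimate), tolerance = 1e-12)
    # cor.test with ties uses the same t approximation
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("tie-free rs equals the classical 1 - 6*sum(d^2)/(n(n^2-1)) formula", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(4:25, 1)
    x <- sample(seq_len(100), n)
    y <- sample(seq_len(100), n)
    d <- rank(x) - rank(y)
    classical <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
    expect_equal(spearman_cor(x, y)$rs, classical, tolerance = 1e-12)
  }
})

test_that("spearman_cor is symmetric and monotone-transform invariant", {
  set.seed(29)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(spearman_cor(x, y)$rs, spearman_cor(y, x)$rs)
  expect_equal(spearman_cor(exp(x), y)$rs, spearman_cor(x, y)$rs)
  expect_equal(spearman_cor(x, y^3)$rs, spearman_cor(x, y)$rs)
  # strictly monotone pairing gives rs = 1
  expect_equal(spearman_cor(1:8, c(2, 5, 7, 10, 11, 30, 31, 50))$rs, 1)
})

test_that("degenerate inputs are handled: NA pairs, tiny n, zero rank variance", {
  x <- c(1, 2, 3, 4, NA, 6)
  y <- c(2, 1, 4, NA, 5, 6)
  got <- spearman_cor(x, y)
  expect_equal(got$n, 4)
  expect_error(spearman_cor(c(1, 2, NA), c(1, 2, 3)), "at least 3")
  allsame <- spearman_cor(c(5, 5, 5, 5), 1:4)
  expect_true(is.na(allsame$rs))
})

test_that("exact permutation p-values match the reference exact distribution", {
  set.seed(41)
  for (i in 1:5) {
    n <- sample(5:7, 1)
    x <- sample(100, n); y <- sample(100, n)
    pex <- spearman_cor(x, y, p_method = "exact")$p_value
    ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    expect_equal(pex, ref, tolerance = 1e-12)
  }
  expect_error(spearman_cor(rnorm(9), rnorm(9), p_method = "exact"), "n <= 8")
})

test_that("the correlation grid joins, stars, and drops undefined cells pairwise", {
  set.seed(3)
  n <- 12
  subj <- sprintf("s%02d", 1:n)
  score_val <- sample(10:55, n)
  mk_rows <- function(signal, value) {
    tibble::tibble(subject_id = subj, session = "baseline", affected = TRUE,
                   domain = "4", signal = signal, average_mss = value,
                   performance_time_s = 100 - score_val + rnorm(n))
  }
  mss_rows <- dplyr::bind_rows(
    mk_rows("roll", score_val + rnorm(n)),             # strong positive
    mk_rows("pitch", replace(score_val + rnorm(n), 1:2, NA)),  # partial NA
    dplyr::bind_rows(lapply(c("yaw", "accel_x", "accel_y", "accel_z"),
                            function(s) mk_rows(s, rnorm(n))))
  )
  scores <- tibble::tibble(subject_id = subj, session = "baseline",
                           arat = score_val)
  grid <- correlation_table(mss_rows, scores)
  expect_s3_class(grid, "mss_correlation")
  expect_equal(nrow(grid), 7)  # one domain x 7 parameters
  roll <- grid[grid$parameter == "roll", ]
  expect_gt(roll$rs, 0.9)
  expect_equal(roll$sig, "**")
  # pairwise deletion: pitch keeps the 10 complete pairs
  expect_equal(grid$n[grid$parameter == "pitch"], 10)
  expect_lt(grid$rs[grid$parameter == "performance_time"], -0.9)
  # unmatched sensor rows are an explicit join error
  expect_error(correlation_table(mss_rows, scores[-1, ]), "without matching scores")
})

test_that("shuffled scores decorrelate the grid", {
  set.seed(31)
  n <- 200  # null sd of rs ~ 1/sqrt(n-1) ~ 0.07, so 0.35 is a ~5 sigma bound
  subj <- sprintf("s%02d", 1:n)
  val <- sort(runif(n, 10, 60))
  mss_rows <- tibble::tibble(subject_id = subj, session = "baseline",
                             affected = TRUE, domain = "1", signal = "roll",
                             average_mss = val, performance_time_s = 50)
  scores <- tibble::tibble(subject_id = subj, session = "baseline",
                           arat = sample(0:57, n, replace = TRUE))
  grid <- correlation_table(mss_rows, scores)
  roll <- grid[grid$parameter == "roll", ]
  expect_lt(abs(roll$rs), 0.35)
  expect_gt(roll$p_value, 0.05)
})

test_that("pre/post changes reproduce the completer case series", {
  ch <- table3_changes()
  expect_equal(sort(ch$parameter), c("pitch", "roll", "yaw"))
  get <- function(p, col) ch[[col]][ch$parameter == p]
  # reported to one decimal place; compare at half an ulp of that precision
  near <- function(got, pub) expect_lt(abs(got - pub), 0.05 + 1e-9)
  near(get("roll", "mean_change"), 11.5)
  near(get("roll", "sd_change"), 14.2)
  near(get("pitch", "mean_change"), 9.1)
  near(get("pitch", "sd_change"), 1.5)
  near(get("yaw", "mean_change"), 24.1)
  near(get("yaw", "sd_change"), 27.9)
  expect_true(all(ch$n == 4))
})

test_that("change summaries exclude incomplete subjects and respect identities", {
  long <- tidyr::expand_grid(subject_id = c("a", "b", "c"),
                             session = c("baseline", "followup"),
                             parameter = "roll")
  long$value <- c(10, 15, 20, 24, 30, 33)  # deltas 5, 4, 3
  ch <- pre_post_changes(long)
  expect_equal(ch$mean_change, 4)
  expect_equal(ch$n, 3)
  # mean of deltas equals difference of session means over completers
  expect_equal(ch$mean_change,
               mean(long$value[long$session == "followup"]) -
                 mean(long$value[long$session == "baseline"]))
  # identical pre/post -> zero change, zero SD
  null_long <- long
  null_long$value <- rep(c(7, 7), 3)
  ch0 <- pre_post_changes(null_long)
  expect_equal(ch0$mean_change, 0)
  expect_equal(ch0$sd_change, 0)
  # a subject missing follow-up is excluded with a warning
  expect_warning(ch2 <- pre_post_changes(long[-2, ]), "missing a session.*a")
  expect_equal(ch2$n, 2)
})
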